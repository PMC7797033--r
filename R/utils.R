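#' @importFrom rlang abort warn .data %||%
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
#'   bind_rows n left_join row_number across
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dfr map_dbl map2
#' @keywords internal
"_PACKAGE"

abort_invalid <- function(msg) abort(msg, class = "curtainr_invalid_parameter")
abort_insufficient <- function(msg) abort(msg, class = "curtainr_insufficient_data")
abort_fit <- function(msg) abort(msg, class = "curtainr_fit_failure")

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_invalid(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort_invalid(sprintf("`%s` must be a single non-negative finite number.", name))
  }
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort_invalid(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort_invalid("`seed` must be a single finite number.")
    }
    set.seed(as.integer(seed))
  }
  invisible(seed)
}

# Sub-stream seed derived from a base seed; stays inside 32-bit range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
}

# Normal draw truncated at zero (exact, via inverse CDF)
rtnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

# Gaussian smoothing of a vector with edge-replicating boundaries
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad <- c(rep(x[1L], half), x, rep(x[n], half))
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}
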