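#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for fitted objects
#'
#' `tidy()` returns one row per estimated parameter (term/estimate);
#' `glance()` returns a one-row model summary.
#'
#' @param x A fitted object (`velocity_fit`, `survival_fit`, `rate_fit`,
#'   `biphasic_fit`, `step_calls`, `experiment_fit`).
#' @param ... Unused.
#' @name curtainr-tidiers
NULL

#' @rdname curtainr-tidiers
#' @export
tidy.velocity_fit <- function(x, ...) {
  tibble(
    term = c("mu", "sigma", "amplitude"),
    estimate = c(x$mu, x$sigma, x$amplitude),
    unit = c("nt/s", "nt/s", "counts")
  )
}

#' @rdname curtainr-tidiers
#' @export
glance.velocity_fit <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, n = x$n,
         bin_width = x$bin_width, residual = x$residual)
}

#' @rdname curtainr-tidiers
#' @export
tidy.survival_fit <- function(x, ...) {
  tibble(
    term = c("lambda", "half_life"),
    estimate = c(x$lambda, x$half_life),
    conf.low = c(log(2) / x$ci[2], x$ci[1]),
    conf.high = c(log(2) / x$ci[1], x$ci[2]),
    unit = c("1/nt", "nt")
  )
}

#' @rdname curtainr-tidiers
#' @export
glance.survival_fit <- function(x, ...) {
  tibble(half_life = x$half_life, ci_lo = x$ci[1], ci_hi = x$ci[2],
         n = x$n, n_boot = x$n_boot, d_min = x$d_min)
}

#' @rdname curtainr-tidiers
#' @export
tidy.rate_fit <- function(x, ...) {
  tibble(term = c("A", "k"), estimate = c(x$A, x$k), unit = c("a.u.", "1/s"))
}

#' @rdname curtainr-tidiers
#' @export
glance.rate_fit <- function(x, ...) {
  tibble(model = x$model, A = x$A, k = x$k, residual = x$residual,
         n = x$n, near_zero_rate = x$near_zero_rate)
}

#' @rdname curtainr-tidiers
#' @export
tidy.biphasic_fit <- function(x, ...) {
  tibble(
    term = c("fast_amp", "fast_k", "slow_amp", "slow_k"),
    estimate = c(x$fast_amp, x$fast_k, x$slow_amp, x$slow_k),
    unit = c("a.u.", "1/s", "a.u.", "1/s")
  )
}

#' @rdname curtainr-tidiers
#' @export
glance.biphasic_fit <- function(x, ...) {
  tibble(fast_amp = x$fast_amp, fast_k = x$fast_k,
         slow_amp = x$slow_amp, slow_k = x$slow_k,
         single = x$single, residual = x$residual)
}

#' @rdname curtainr-tidiers
#' @export
tidy.step_calls <- function(x, ...) {
  tibble(step = seq_len(x$n_steps), time_s = x$step_times, size = x$step_sizes)
}

#' @rdname curtainr-tidiers
#' @export
glance.step_calls <- function(x, ...) {
  tibble(n_steps = x$n_steps, classification = x$classification,
         n_up_flagged = x$n_up_flagged, sigma = x$sigma)
}

#' @rdname curtainr-tidiers
#' @export
glance.experiment_fit <- function(x, ...) {
  tibble(
    preset = x$preset$name %||% NA_character_,
    velocity_mu = x$velocity_fit$mu,
    velocity_sigma = x$velocity_fit$sigma,
    half_life = x$survival_fit$half_life,
    half_life_lo = x$survival_fit$ci[1],
    half_life_hi = x$survival_fit$ci[2],
    n_events = x$velocity_fit$n,
    n_uncensored = x$survival_fit$n,
    monomers_per_s = monomers_per_second(x$velocity_fit$mu),
    seed = x$seed
  )
}
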