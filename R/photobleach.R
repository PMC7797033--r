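# Best single split of y[lo:hi] by RSS reduction; returns c(split, gain).
best_split <- function(y, lo, hi) {
  n <- hi - lo + 1L
  if (n < 2L) return(c(NA_integer_, 0))
  seg <- y[lo:hi]
  cs <- cumsum(seg); tot <- cs[n]
  k <- seq_len(n - 1L)
  sse_full <- sum(seg^2) - tot^2 / n
  left <- cs[k]; right <- tot - left
  sse_split <- (sum(seg^2)) - left^2 / k - right^2 / (n - k)
  gains <- sse_full - sse_split
  kbest <- which.max(gains)
  c(lo + kbest - 1L, gains[kbest])
}

# Penalised binary segmentation: returns sorted changepoint indices
# (last index of each left segment).
binseg_changepoints <- function(y, penalty) {
  cps <- integer(0)
  queue <- list(c(1L, length(y)))
  while (length(queue)) {
    seg <- queue[[1L]]; queue <- queue[-1L]
    bs <- best_split(y, seg[1L], seg[2L])
    if (!is.na(bs[1L]) && bs[2L] > penalty) {
      cp <- as.integer(bs[1L])
      cps <- c(cps, cp)
      queue <- c(queue, list(c(seg[1L], cp)), list(c(cp + 1L, seg[2L])))
    }
  }
  sort(cps)
}

#' Count photobleaching steps in an intensity trace
#'
#' Fits a piecewise-constant model to the trace by penalised binary
#' segmentation (penalty scaled to a robust noise estimate), then counts
#' downward level changes larger than a minimum step size as bleaching
#' steps. Upward level changes (blinking / rebinding) are flagged but never
#' counted. A punctum is classified `multi` when two or more steps are
#' detected.
#'
#' @param trace An `intensity_trace` (tibble with `time_s`, `intensity`),
#'   at least 20 points.
#' @param penalty_scale Multiplier on the `sigma^2 * log(n)` segmentation
#'   penalty; larger values yield fewer detected steps.
#' @param min_step_size Minimum |level change| to count as a step; default
#'   `3 * sigma` with `sigma` the robust noise SD.
#' @return A `step_calls` object: `n_steps`, `step_times`, `step_sizes`
#'   (negative, downward), `n_up_flagged`, `classification`
#'   (`"single"`/`"multi"`/`"none"`), `levels` tibble, `sigma`.
#' @export
count_steps <- function(trace, penalty_scale = 2, min_step_size = NULL) {
  tr <- as_tibble(trace)
  stopifnot(all(c("time_s", "intensity") %in% names(tr)))
  n <- nrow(tr)
  if (n < 20L) abort_insufficient("Trace must have at least 20 points.")
  check_positive(penalty_scale, "penalty_scale")
  y <- tr$intensity

  sigma <- stats::mad(diff(y)) / sqrt(2)
  sigma_floor <- max(1e-9, 1e-6 * max(abs(y), 1))
  sigma_eff <- max(sigma, sigma_floor)
  if (is.null(min_step_size)) min_step_size <- 3 * sigma
  penalty <- penalty_scale * sigma_eff^2 * log(n)

  cps <- binseg_changepoints(y, penalty)
  bounds <- c(0L, cps, n)
  lev <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(y[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))

  # merge adjacent levels whose change is below the step-size threshold
  keep_cp <- abs(diff(lev)) >= max(min_step_size, sigma_floor)
  cps <- cps[keep_cp]
  bounds <- c(0L, cps, n)
  lev <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(y[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  dlev <- diff(lev)

  down <- which(dlev < 0)
  up <- which(dlev > 0)
  n_steps <- length(down)
  structure(
    list(
      n_steps = n_steps,
      step_times = tr$time_s[cps[down]],
      step_sizes = dlev[down],
      n_up_flagged = length(up),
      classification = if (n_steps >= 2L) "multi" else if (n_steps == 1L) "single" else "none",
      levels = tibble(
        start_idx = bounds[-length(bounds)] + 1L,
        end_idx = bounds[-1L],
        level = lev
      ),
      sigma = sigma,
      trace = tr
    ),
    class = "step_calls"
  )
}

#' @export
print.step_calls <- function(x, ...) {
  cat(sprintf("<step_calls> %d bleaching step(s) (%s)%s\n",
              x$n_steps, x$classification,
              if (x$n_up_flagged) sprintf(", %d upward change(s) flagged", x$n_up_flagged) else ""))
  invisible(x)
}

#' Summarise a photobleaching cohort
#'
#' Tabulates the fraction of puncta with a single bleaching step versus two
#' or more steps, each with its numerator and denominator.
#'
#' @param results List of `step_calls` objects (>= 1).
#' @return Tibble with `classification`, `n`, `total`, `percent`.
#' @export
classify_cohort <- function(results) {
  if (length(results) == 0L) abort_insufficient("No step-call results supplied.")
  cls <- vapply(results, function(r) {
    stopifnot(inherits(r, "step_calls"))
    r$classification
  }, character(1))
  total <- length(cls)
  tibble(
    classification = c("single", "multi", "none"),
    n = c(sum(cls == "single"), sum(cls == "multi"), sum(cls == "none")),
    total = total
  ) |>
    mutate(percent = 100 * .data$n / .data$total)
}
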