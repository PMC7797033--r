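#' Segment a raw sensorgram into labeled protocol phases
#'
#' Assigns every sample of a time/signal series to a phase of the BLI
#' protocol according to a schedule of phase start times, so that the
#' dissociation phase can be isolated for analysis.
#'
#' @param raw Data frame with `time_s` and `signal_nm`, strictly increasing
#'   time.
#' @param schedule Data frame with `label` and `start_s` (strictly
#'   increasing); start times must lie within the series span.
#' @return A `sensorgram`: tibble (`time_s`, `signal_nm`, `phase`) with the
#'   schedule stored in `attr(, "schedule")`.
#' @export
segment_phases <- function(raw, schedule) {
  raw <- as_tibble(raw)
  schedule <- as_tibble(schedule)
  stopifnot(all(c("time_s", "signal_nm") %in% names(raw)),
            all(c("label", "start_s") %in% names(schedule)))
  if (any(diff(raw$time_s) <= 0)) abort_invalid("`time_s` must be strictly increasing.")
  if (any(diff(schedule$start_s) <= 0)) {
    abort_invalid("Schedule start times must be strictly increasing.")
  }
  if (min(schedule$start_s) < min(raw$time_s) - 1e-9 ||
      max(schedule$start_s) > max(raw$time_s) + 1e-9) {
    abort("Schedule lies outside the sampled time span.", class = "curtainr_bounds_error")
  }
  idx <- findInterval(raw$time_s, schedule$start_s)
  out <- raw
  out$phase <- ifelse(idx >= 1L, schedule$label[pmax(idx, 1L)], NA_character_)
  structure(out, class = c("sensorgram", class(tibble())), schedule = schedule)
}

#' @export
print.sensorgram <- function(x, ...) {
  sch <- attr(x, "schedule")
  cat(sprintf("<sensorgram> %d samples, phases: %s\n",
              nrow(x), paste(sch$label, collapse = " -> ")))
  NextMethod()
}

dissociation_phase <- function(x) {
  stopifnot(inherits(x, "sensorgram"))
  d <- x |> filter(.data$phase == "dissociation")
  if (nrow(d) == 0L) {
    abort("Sensorgram has no labeled dissociation phase.",
          class = "curtainr_phase_absent")
  }
  d
}

#' Normalise dissociation phases and subtract a control
#'
#' Each dissociation trace is normalised to its starting point, then the
#' control (peptide-only) trace is subtracted pointwise, isolating the
#' motor-dependent component of recombinase removal. Normalisation is
#' either `fraction` (divide by the first value, expressed as % of the
#' start) or `offset` (subtract the first value, leaving nm change; the
#' mode in which subtracting a flat control is exactly a no-op). Both
#' traces must share the same dissociation-phase sampling; no silent
#' interpolation is done.
#'
#' @param test,control `sensorgram` objects with dissociation phases.
#' @param mode `"fraction"` (%) or `"offset"` (nm).
#' @return Tibble with `time_s` (from dissociation start), `norm_test`,
#'   `norm_control`, `pct_change` (test minus control; % in `fraction`
#'   mode, nm in `offset` mode).
#' @export
normalize_and_subtract <- function(test, control, mode = c("fraction", "offset")) {
  mode <- match.arg(mode)
  dt <- dissociation_phase(test)
  dc <- dissociation_phase(control)
  if (nrow(dt) != nrow(dc) ||
      max(abs((dt$time_s - dt$time_s[1L]) - (dc$time_s - dc$time_s[1L]))) > 1e-6) {
    abort("Dissociation phases are sampled differently; resample before subtracting.",
          class = "curtainr_resample_required")
  }
  if (mode == "fraction") {
    if (dt$signal_nm[1L] == 0 || dc$signal_nm[1L] == 0) {
      abort_invalid("Dissociation phase starts at zero signal; cannot normalise.")
    }
    nt <- 100 * dt$signal_nm / dt$signal_nm[1L]
    nc <- 100 * dc$signal_nm / dc$signal_nm[1L]
  } else {
    nt <- dt$signal_nm - dt$signal_nm[1L]
    nc <- dc$signal_nm - dc$signal_nm[1L]
  }
  tibble(
    time_s = dt$time_s - dt$time_s[1L],
    norm_test = nt,
    norm_control = nc,
    pct_change = nt - nc
  )
}

#' Fit a biphasic exponential to a dissociation trace
#'
#' Fits `y(t) = fast_amp e^{-fast_k t} + slow_amp e^{-slow_k t}` by
#' nonlinear least squares with the ordering constraint
#' `fast_k > slow_k`. Starting values come from curve peeling: the tail is
#' fit first for the slow component, then the residual head for the fast
#' one. If the two rates are not separable (ratio < 3) a model-selection
#' warning is raised and a single-exponential fit is returned instead when
#' it is preferred by AIC.
#'
#' @param trace Tibble with `time_s` and a signal column (`signal_nm`,
#'   `pct_change` or `intensity`), e.g. a dissociation phase or the output
#'   of [normalize_and_subtract()].
#' @return A `biphasic_fit` object: `fast_amp`, `fast_k`, `slow_amp`,
#'   `slow_k`, `single` (fallback flag), `residual`, `fitted`.
#' @export
fit_biphasic <- function(trace) {
  tr <- as_tibble(trace)
  ycol <- intersect(c("signal_nm", "pct_change", "intensity"), names(tr))[1]
  if (is.na(ycol)) abort_invalid("No signal column found in `trace`.")
  t <- tr$time_s - tr$time_s[1L]
  y <- tr[[ycol]]
  if (length(y) < 10L) abort_insufficient("Need at least 10 points.")
  if (diff(range(y)) < 1e-12 * max(abs(y), 1)) {
    abort_fit("Trace is flat: no decay to fit.")
  }

  # curve peeling for starts
  tail_idx <- t >= stats::quantile(t, 0.5)
  ytail <- pmax(y[tail_idx], 1e-12)
  slow_lm <- stats::lm(log(ytail) ~ t[tail_idx])
  slow_k0 <- max(-stats::coef(slow_lm)[[2L]], 1e-8)
  slow_a0 <- max(exp(stats::coef(slow_lm)[[1L]]), 1e-8)
  resid_head <- y - slow_a0 * exp(-slow_k0 * t)
  head_idx <- which(t <= stats::quantile(t, 0.25) & resid_head > 0)
  if (length(head_idx) >= 3L) {
    fast_lm <- stats::lm(log(resid_head[head_idx]) ~ t[head_idx])
    fast_k0 <- max(-stats::coef(fast_lm)[[2L]], slow_k0 * 5)
    fast_a0 <- max(exp(stats::coef(fast_lm)[[1L]]), 1e-8)
  } else {
    fast_k0 <- slow_k0 * 10
    fast_a0 <- max(y[1L] - slow_a0, 0.1 * abs(y[1L]))
  }

  dat <- tibble(t = t, y = y)
  bi <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fa * exp(-fk * t) + sa * exp(-sk * t), data = dat,
      start = list(fa = fast_a0, fk = fast_k0, sa = slow_a0, sk = slow_k0),
      lower = c(fa = 0, fk = 0, sa = 0, sk = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  single <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-k * t), data = dat,
      start = list(a = max(y[1L], 1e-8), k = slow_k0),
      lower = c(a = 0, k = 0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(bi) && is.null(single)) abort_fit("Biphasic fit did not converge.")

  use_single <- FALSE
  if (!is.null(bi)) {
    cf <- stats::coef(bi)
    ks <- sort(c(cf[["fk"]], cf[["sk"]]), decreasing = TRUE)
    ratio <- if (ks[2] > 0) ks[1] / ks[2] else Inf
    amps <- c(cf[["fa"]], cf[["sa"]])
    if (!is.null(single) && min(amps) < 0.01 * sum(amps)) {
      # one component is negligible: the trace is effectively single-exponential
      use_single <- TRUE
    } else if (ratio < 3 && !is.null(single)) {
      warn("Fast and slow rates are not separable (ratio < 3); comparing to a single exponential.",
           class = "curtainr_model_selection")
      use_single <- stats::AIC(single) <= stats::AIC(bi)
    }
  } else {
    use_single <- TRUE
  }

  if (use_single) {
    cf <- stats::coef(single)
    out <- list(
      fast_amp = unname(cf["a"]), fast_k = unname(cf["k"]),
      slow_amp = 0, slow_k = 0, single = TRUE,
      residual = sum(stats::resid(single)^2),
      fitted = tibble(time_s = t, y = y, fitted = stats::predict(single))
    )
  } else {
    cf <- stats::coef(bi)
    comps <- tibble(amp = c(cf[["fa"]], cf[["sa"]]), k = c(cf[["fk"]], cf[["sk"]])) |>
      arrange(dplyr::desc(.data$k))
    out <- list(
      fast_amp = comps$amp[1L], fast_k = comps$k[1L],
      slow_amp = comps$amp[2L], slow_k = comps$k[2L], single = FALSE,
      residual = sum(stats::resid(bi)^2),
      fitted = tibble(time_s = t, y = y, fitted = stats::predict(bi))
    )
  }
  structure(out, class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  if (x$single) {
    cat(sprintf("<biphasic_fit> single-exponential fallback: A = %.3g, k = %.3g 1/s\n",
                x$fast_amp, x$fast_k))
  } else {
    cat(sprintf("<biphasic_fit> fast: %.3g @ %.3g 1/s; slow: %.3g @ %.3g 1/s\n",
                x$fast_amp, x$fast_k, x$slow_amp, x$slow_k))
  }
  invisible(x)
}
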