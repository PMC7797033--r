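#' Fit a Gaussian to a binned velocity distribution
#'
#' Velocities are binned in `bin_width` nt/s bins anchored at 0 and the
#' histogram counts are fit to a Gaussian `A * exp(-(v - mu)^2 / (2 sigma^2))`
#' by unweighted least squares, mirroring the standard presentation of
#' single-molecule translocation velocities. The reported value is
#' `mu +/- sigma`.
#'
#' @param velocities Numeric vector of event velocities, nt/s (>= 10 values).
#' @param bin_width Histogram bin width, nt/s.
#' @return A `velocity_fit` object with elements `mu`, `sigma`, `amplitude`,
#'   `n`, `bin_width`, `bins` (tibble: `mid`, `count`, `fitted`), `residual`.
#' @export
fit_velocity_distribution <- function(velocities, bin_width = 15) {
  velocities <- velocities[is.finite(velocities)]
  if (length(velocities) < 10L) {
    abort_insufficient("Need at least 10 velocities for a Gaussian fit.")
  }
  if (stats::sd(velocities) == 0) {
    abort_fit("All velocities identical: Gaussian fit is degenerate.")
  }
  check_positive(bin_width, "bin_width")
  # bins aligned to multiples of bin_width, anchored at 0
  breaks <- seq(floor(min(velocities, 0) / bin_width) * bin_width,
                max(velocities) + bin_width, by = bin_width)
  h <- graphics::hist(velocities, breaks = breaks, plot = FALSE)
  bins <- tibble(mid = h$mids, count = h$counts)

  start <- list(A = max(bins$count), mu = mean(velocities), sigma = stats::sd(velocities))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2)),
      data = bins, start = start,
      lower = c(A = 1e-8, mu = 0, sigma = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort_fit(paste0("Gaussian histogram fit failed: ", conditionMessage(e)))
  )
  cf <- stats::coef(fit)
  bins$fitted <- stats::predict(fit)
  structure(
    list(
      mu = unname(cf["mu"]), sigma = unname(cf["sigma"]),
      amplitude = unname(cf["A"]), n = length(velocities),
      bin_width = bin_width, bins = bins,
      residual = sum(stats::resid(fit)^2), velocities = velocities
    ),
    class = "velocity_fit"
  )
}

#' @export
print.velocity_fit <- function(x, ...) {
  cat(sprintf("<velocity_fit> %.1f +/- %.1f nt/s (N = %d, %g nt/s bins)\n",
              x$mu, x$sigma, x$n, x$bin_width))
  invisible(x)
}

#' Empirical survival curve of translocation distances
#'
#' `S(d)` is the fraction of events whose distance is at least `d`,
#' evaluated at each distinct observed distance; `S` is 1 before the
#' smallest distance.
#'
#' @param distances Positive translocation distances, nt.
#' @return Tibble with `distance_nt` and `survival`, sorted by distance.
#' @export
survival_curve <- function(distances) {
  distances <- distances[is.finite(distances)]
  if (length(distances) == 0L) {
    abort_insufficient("No distances supplied.")
  }
  if (any(distances <= 0)) abort_invalid("Distances must be positive.")
  d <- sort(unique(distances))
  s <- vapply(d, function(x) mean(distances >= x), numeric(1))
  tibble(distance_nt = d, survival = s)
}

# least-squares decay constant of an empirical survival curve; optimisation
# is on log(lambda) because lambda (1/nt) is far below optimize()'s default
# absolute tolerance
ls_exponential_halflife <- function(distances, d_min = 0) {
  sc <- survival_curve(distances)
  d_eff <- pmax(sc$distance_nt - d_min, 0)
  f <- function(loglam) sum((sc$survival - exp(-exp(loglam) * d_eff))^2)
  lo <- log(1e-7 / max(distances))
  up <- log(50 / stats::median(distances))
  opt <- stats::optimize(f, c(lo, up), tol = 1e-10)
  lam <- exp(opt$minimum)
  if (opt$minimum <= lo + 1e-6 || !is.finite(lam)) {
    abort_fit("Survival curve does not decay: exponential fit failed.")
  }
  lam
}

#' Fit a single-exponential survival curve and report processivity
#'
#' The empirical survival of translocation distances is fit to
#' `S(d) = exp(-lambda d)` (amplitude fixed at 1) by least squares; the
#' reported processivity is the half-life `log(2) / lambda`. Confidence
#' intervals come from a nonparametric bootstrap: distances are resampled
#' with replacement, refit, and the 95% percentile interval of the
#' resampled half-lives is returned.
#'
#' @param distances Uncensored translocation distances, nt (>= 10 values).
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param conf_level Confidence level for the percentile interval.
#' @param d_min Detection threshold, nt: events shorter than this are
#'   unobservable, so the survival model is `exp(-lambda (d - d_min))`. By
#'   the memorylessness of the exponential this removes the left-truncation
#'   bias that a minimum-displacement event filter would otherwise inject
#'   into the half-life. `0` fits the plain `exp(-lambda d)`.
#' @return A `survival_fit` object with `lambda` (1/nt), `half_life` (nt),
#'   `ci` (length-2 vector), `curve` (tibble from [survival_curve()]),
#'   `n`, `n_boot`, `seed`.
#' @export
fit_processivity <- function(distances, n_boot = 1000, seed = NULL,
                             conf_level = 0.95, d_min = 0) {
  distances <- distances[is.finite(distances)]
  if (length(distances) < 10L) {
    abort_insufficient("Need at least 10 uncensored distances for a survival fit.")
  }
  if (any(distances <= 0)) abort_invalid("Distances must be positive.")
  if (length(unique(distances)) == 1L) {
    abort_fit("All distances identical: survival fit is degenerate.")
  }
  lam <- ls_exponential_halflife(distances, d_min = d_min)
  set_seed_if(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    resampled <- sample(distances, replace = TRUE)
    if (length(unique(resampled)) == 1L) return(NA_real_)
    log(2) / ls_exponential_halflife(resampled, d_min = d_min)
  }, numeric(1))
  boots <- boots[is.finite(boots)]
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  structure(
    list(
      lambda = lam, half_life = log(2) / lam, ci = ci,
      curve = survival_curve(distances), distances = distances,
      n = length(distances), n_boot = n_boot, seed = seed,
      conf_level = conf_level, d_min = d_min
    ),
    class = "survival_fit"
  )
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf(
    "<survival_fit> half-life = %.0f nt (%.0f%% CI %.0f-%.0f, N = %d, %d bootstrap resamples)\n",
    x$half_life, 100 * x$conf_level, x$ci[1], x$ci[2], x$n, x$n_boot
  ))
  invisible(x)
}

#' Fit an exponential decay or recovery to an intensity trace
#'
#' Fits `I = A exp(-k t)` (decay of a fluorescent coat during filament
#' assembly) or `I = A (1 - exp(-k t))` (recovery of coat fluorescence
#' during filament disassembly) by nonlinear least squares. `k` is the
#' observed exchange rate: coat disassembly rate equals recombinase
#' assembly rate, and coat recovery rate equals recombinase dissociation
#' rate. Initialisation: `A` from the first point (decay) or final plateau
#' (recovery), `k` from a log-linear regression over the first decade of
#' the transient.
#'
#' @param trace Tibble with `time_s` and `intensity` (an `intensity_trace`).
#' @param model `"decay"` or `"recovery"`.
#' @return A `rate_fit` object with `model`, `A`, `k` (1/s), `residual`,
#'   `n`, `near_zero_rate` flag, `fitted` tibble.
#' @export
fit_exchange_rate <- function(trace, model = c("decay", "recovery")) {
  model <- match.arg(model)
  tr <- as_tibble(trace)
  stopifnot(all(c("time_s", "intensity") %in% names(tr)))
  if (nrow(tr) < 10L) abort_insufficient("Need at least 10 time points.")
  t <- tr$time_s; y <- tr$intensity

  rng <- diff(range(y))
  if (rng < 1e-12 * max(abs(y), 1)) {
    warn("Trace is flat: returning rate ~ 0.", class = "curtainr_near_zero_rate")
    return(structure(
      list(model = model, A = mean(y), k = 0, residual = sum((y - mean(y))^2),
           n = length(y), near_zero_rate = TRUE,
           fitted = tibble(time_s = t, intensity = y, fitted = mean(y))),
      class = "rate_fit"
    ))
  }

  if (model == "decay") {
    A0 <- max(y[1L], 1e-8)
    use <- which(y > A0 / 10 & y > 0)
    k0 <- if (length(use) >= 2L) {
      max(-stats::coef(stats::lm(log(y[use]) ~ t[use]))[[2L]], 1e-6)
    } else 1 / max(t)
    form <- intensity ~ A * exp(-k * time_s)
    start <- list(A = A0, k = k0)
  } else {
    A0 <- max(mean(y[t >= stats::quantile(t, 0.9)]), max(y), 1e-8)
    frac <- pmin(pmax(1 - y / A0, 1e-6), 1)
    use <- which(frac > 0.1)
    k0 <- if (length(use) >= 2L) {
      max(-stats::coef(stats::lm(log(frac[use]) ~ t[use]))[[2L]], 1e-6)
    } else 1 / max(t)
    form <- intensity ~ A * (1 - exp(-k * time_s))
    start <- list(A = A0, k = k0)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = tr, start = start,
                      lower = c(A = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      abort_fit(paste0("Exponential ", model, " fit failed: ", conditionMessage(e),
                       " (start A=", signif(start$A, 3), ", k=", signif(start$k, 3), ")"))
    }
  )
  cf <- stats::coef(fit)
  near_zero <- cf[["k"]] < 1e-8
  if (near_zero) warn("Fitted rate is ~ 0.", class = "curtainr_near_zero_rate")
  structure(
    list(
      model = model, A = unname(cf["A"]), k = unname(cf["k"]),
      residual = sum(stats::resid(fit)^2), n = nrow(tr),
      near_zero_rate = near_zero,
      fitted = tibble(time_s = t, intensity = y, fitted = stats::predict(fit))
    ),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> %s: A = %.3g, k = %.3g 1/s (n = %d)\n",
              x$model, x$A, x$k, x$n))
  invisible(x)
}

#' Recombinase monomer accounting
#'
#' Converts a translocation velocity (nt/s) or processivity (nt) into
#' recombinase monomers removed per second or per translocation event,
#' assuming one monomer bound per `footprint` nucleotides (3 nt/monomer for
#' RecA-family filaments). Rounding is left to the presentation layer.
#'
#' @param velocity Translocation velocity, nt/s.
#' @param processivity Processivity, nt.
#' @param footprint Nucleotides occupied per monomer (> 0).
#' @return Monomers per second (resp. per event).
#' @export
monomers_per_second <- function(velocity, footprint = 3) {
  check_positive(footprint, "footprint")
  if (any(velocity < 0)) abort_invalid("`velocity` must be non-negative.")
  velocity / footprint
}

#' @rdname monomers_per_second
#' @export
monomers_per_event <- function(processivity, footprint = 3) {
  check_positive(footprint, "footprint")
  if (any(processivity < 0)) abort_invalid("`processivity` must be non-negative.")
  processivity / footprint
}
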