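#' Kymograph container
#'
#' A kymograph is a time-by-position intensity matrix extracted (or rendered)
#' along a 1-pixel-wide line following one ssDNA molecule: rows are frames,
#' columns are pixels along the DNA with pixel 0 at the tethered 5' end.
#'
#' @param data Numeric matrix, frames x pixels.
#' @param imaging An [imaging_model()].
#' @param channel Channel label.
#' @return A `kymograph` object.
#' @export
as_kymograph <- function(data, imaging, channel = "ch1") {
  stopifnot(is.matrix(data), inherits(imaging, "imaging_model"))
  structure(
    list(
      data = data, channel = channel, imaging = imaging,
      frame_times = (seq_len(nrow(data)) - 1L) * imaging$frame_interval
    ),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "<kymograph> channel '%s': %d frames x %d px (%g s/frame, %g nt/px)\n",
    x$channel, nrow(x$data), ncol(x$data),
    x$imaging$frame_interval, x$imaging$nt_per_pixel
  ))
  invisible(x)
}

#' Convert a kymograph to a tidy tibble
#'
#' @param x A `kymograph`.
#' @param ... Unused.
#' @return A tibble with `frame`, `time_s`, `pixel` (0-based), `position_nt`,
#'   `intensity`, `channel`.
#' @export
as_tibble.kymograph <- function(x, ...) {
  nf <- nrow(x$data); np <- ncol(x$data)
  tibble(
    frame = rep(seq_len(nf), times = np),
    time_s = rep(x$frame_times, times = np),
    pixel = rep(0:(np - 1L), each = nf),
    position_nt = rep((0:(np - 1L)) * x$imaging$nt_per_pixel, each = nf),
    intensity = as.vector(x$data),
    channel = x$channel
  )
}

# fraction of each pixel covered by the union of [a_i, b_i] intervals (nt)
interval_coverage <- function(a, b, n_pixels, nt_per_pixel) {
  cov <- numeric(n_pixels)
  if (length(a) == 0L) return(cov)
  edges <- (0:n_pixels) * nt_per_pixel
  for (i in seq_along(a)) {
    lo <- pmin(pmax(edges[-length(edges)], a[i]), b[i])
    hi <- pmin(pmax(edges[-1L], a[i]), b[i])
    cov <- cov + pmax(hi - lo, 0) / nt_per_pixel
  }
  pmin(cov, 1)
}

apply_camera_noise <- function(mu, imaging) {
  x <- mu
  if (imaging$photon_gain > 0) {
    x <- stats::rpois(length(mu), lambda = pmax(mu, 0) * imaging$photon_gain) / imaging$photon_gain
  }
  if (imaging$read_noise > 0) {
    x <- x + stats::rnorm(length(mu), 0, imaging$read_noise)
  }
  pmax(matrix(x + imaging$baseline, nrow = nrow(mu)), 0)
}

#' Render a simulated experiment as kymographs
#'
#' Produces the per-channel kymographs implied by a ground-truth event log:
#' in `clearing` mode the coat channel starts uniformly bright and drops to
#' background behind each motor front; in `exchange` mode a trail channel
#' rises behind each motor. A labeled motor adds a diffraction-limited
#' punctum channel at the motor position. Coverage profiles are blurred with
#' the Gaussian PSF; camera noise is Poisson shot noise at `photon_gain` plus
#' Gaussian read noise (both zero renders noise-free).
#'
#' @param truth A `truth_log` from [simulate_translocation_events()].
#' @param imaging An [imaging_model()] covering the same lattice.
#' @param channels Channel labels; defaults derive from the motor mode
#'   (`coat` or `trail`, plus `motor` when the motor is labeled).
#' @param seed Optional RNG seed for the camera noise.
#' @return Named list of [as_kymograph()] objects.
#' @export
render_kymograph <- function(truth, imaging, channels = NULL, seed = NULL) {
  stopifnot(inherits(truth, "truth_log"), inherits(imaging, "imaging_model"))
  motor <- attr(truth, "motor")
  L <- attr(truth, "ssDNA_length")
  if (imaging$n_pixels * imaging$nt_per_pixel < L) {
    abort("Imaging lattice does not cover the ssDNA length.",
          class = "curtainr_config_error")
  }
  if (is.null(channels)) {
    channels <- c(if (motor$mode == "clearing") "coat" else "trail",
                  if (motor$motor_labeled) "motor")
  }
  if (anyDuplicated(channels)) {
    abort("Duplicate channel labels.", class = "curtainr_config_error")
  }
  set_seed_if(seed)

  times <- seq(0, attr(truth, "duration"), by = imaging$frame_interval)
  nf <- length(times); np <- imaging$n_pixels
  coat_needed <- any(c("coat", "trail") %in% channels)

  coverage <- matrix(0, nf, np)
  motor_mu <- matrix(0, nf, np)
  px_centers <- (0:(np - 1L)) + 0.5
  if (nrow(truth) > 0L) {
    for (i in seq_len(nrow(truth))) {
      ev <- truth[i, ]
      pos <- motor_position_nt(ev, times)
      bound <- !is.na(pos)
      if (coat_needed && any(bound)) {
        for (f in which(bound)) {
          coverage[f, ] <- pmin(1, coverage[f, ] + interval_coverage(
            pos[f], ev$bind_position_nt, np, imaging$nt_per_pixel
          ))
        }
      }
      if (motor$motor_labeled && any(bound)) {
        p_px <- pos / imaging$nt_per_pixel
        sig <- max(imaging$psf_sigma, 1e-6)
        for (f in which(bound)) {
          motor_mu[f, ] <- motor_mu[f, ] +
            imaging$brightness * exp(-(px_centers - p_px[f])^2 / (2 * sig^2))
        }
      }
    }
  }

  out <- list()
  for (ch in channels) {
    mu <- switch(ch,
      coat = imaging$brightness * (1 - coverage),
      trail = imaging$brightness * coverage,
      motor = motor_mu,
      abort(sprintf("Unknown channel label '%s'.", ch), class = "curtainr_config_error")
    )
    if (ch %in% c("coat", "trail") && imaging$psf_sigma > 0) {
      mu <- t(apply(mu, 1L, gauss_smooth, sigma = imaging$psf_sigma))
    }
    out[[ch]] <- as_kymograph(apply_camera_noise(mu, imaging), imaging, channel = ch)
  }
  out
}
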