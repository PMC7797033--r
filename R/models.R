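#' Ground-truth kinetic model of a translocating motor
#'
#' Describes the motor protein used by the simulators: per-molecule velocity
#' is drawn from a Gaussian truncated at zero, run length from an exponential
#' parameterised by its half-life (so the half-life fitted from a survival
#' plot of run lengths recovers `processivity_halflife` directly), and binding
#' is Poisson in time and uniform along the ssDNA. Polarity is fixed 3'->5':
#' motors move toward the tethered 5' end at coordinate 0.
#'
#' @param velocity_mean Mean translocation velocity, nt/s (> 0).
#' @param velocity_sd Standard deviation of per-molecule velocity, nt/s.
#' @param processivity_halflife Half-life of the run-length distribution, nt.
#'   Run lengths are exponential with scale `processivity_halflife / log(2)`.
#' @param binding_rate Binding events per knt of ssDNA per second.
#' @param mode `"clearing"` (fluorescent coat is removed behind the motor) or
#'   `"exchange"` (a fluorescent trail is deposited behind the motor).
#' @param motor_labeled Is the motor itself fluorescent (rendered as a
#'   diffraction-limited punctum)?
#'
#' @return A `motor_model` object (list).
#' @export
motor_model <- function(velocity_mean, velocity_sd, processivity_halflife,
                        binding_rate = 0.002, mode = c("clearing", "exchange"),
                        motor_labeled = FALSE) {
  mode <- match.arg(mode)
  check_positive(velocity_mean, "velocity_mean")
  check_nonnegative(velocity_sd, "velocity_sd")
  check_positive(processivity_halflife, "processivity_halflife")
  check_nonnegative(binding_rate, "binding_rate")
  structure(
    list(
      velocity_mean = velocity_mean, velocity_sd = velocity_sd,
      processivity_halflife = processivity_halflife,
      binding_rate = binding_rate, polarity = "3to5", mode = mode,
      motor_labeled = isTRUE(motor_labeled)
    ),
    class = "motor_model"
  )
}

#' @export
print.motor_model <- function(x, ...) {
  cat(sprintf(
    "<motor_model> v = %g +/- %g nt/s, processivity half-life = %g nt, %s mode%s\n",
    x$velocity_mean, x$velocity_sd, x$processivity_halflife, x$mode,
    if (x$motor_labeled) ", labeled motor" else ""
  ))
  invisible(x)
}

#' Optical/camera model of the curtain microscope
#'
#' @param frame_interval Time between frames, s.
#' @param integration Camera integration time, ms (metadata only; the laser is
#'   shuttered between frames so one frame is one snapshot).
#' @param nt_per_pixel Conversion factor from pixels along the ssDNA axis to
#'   nucleotides.
#' @param n_pixels Number of pixels along the ssDNA long axis.
#' @param psf_sigma Gaussian point-spread-function sigma, pixels.
#' @param photon_gain Expected photons per unit brightness; shot noise is
#'   Poisson at this gain. `0` disables shot noise (noise-free rendering).
#' @param read_noise Gaussian camera read noise (a.u.); `0` disables it.
#' @param brightness Mean signal (a.u.) of a fully coated pixel / punctum peak.
#' @param baseline Camera bias offset (a.u.) added to every pixel. Real
#'   cameras add one so that read noise is not clipped at zero; a clipped
#'   dark background would break any noise estimator downstream.
#'
#' @return An `imaging_model` object.
#' @export
imaging_model <- function(frame_interval = 10, integration = 100,
                          nt_per_pixel = 725, n_pixels = 70, psf_sigma = 1.0,
                          photon_gain = 1, read_noise = 1, brightness = 100,
                          baseline = 10) {
  check_positive(frame_interval, "frame_interval")
  check_positive(nt_per_pixel, "nt_per_pixel")
  check_positive(n_pixels, "n_pixels")
  check_nonnegative(psf_sigma, "psf_sigma")
  check_nonnegative(photon_gain, "photon_gain")
  check_nonnegative(read_noise, "read_noise")
  check_positive(brightness, "brightness")
  check_nonnegative(baseline, "baseline")
  structure(
    list(
      frame_interval = frame_interval, integration = integration,
      nt_per_pixel = nt_per_pixel, n_pixels = as.integer(n_pixels),
      psf_sigma = psf_sigma, photon_gain = photon_gain,
      read_noise = read_noise, brightness = brightness,
      baseline = baseline
    ),
    class = "imaging_model"
  )
}

#' @export
print.imaging_model <- function(x, ...) {
  cat(sprintf(
    "<imaging_model> %g s/frame, %g nt/px, %d px, PSF sigma %g px\n",
    x$frame_interval, x$nt_per_pixel, x$n_pixels, x$psf_sigma
  ))
  invisible(x)
}

#' Noise-free variant of an imaging model
#'
#' @param imaging An [imaging_model()].
#' @return The same model with shot and read noise zeroed.
#' @export
noise_free <- function(imaging) {
  imaging$photon_gain <- 0
  imaging$read_noise <- 0
  imaging
}

#' Pixel-to-nucleotide conversion
#'
#' @param x Position or distance in pixels.
#' @param imaging An [imaging_model()].
#' @return `x * nt_per_pixel`, in nucleotides.
#' @export
px_to_nt <- function(x, imaging) {
  stopifnot(inherits(imaging, "imaging_model"))
  x * imaging$nt_per_pixel
}

#' Probabilistic model of motor encounters with a heteroduplex DNA joint
#'
#' A stationary heteroduplex joint (D-loop) sits on the RAD51-ssDNA at
#' `heteroduplex_position`. A motor either binds directly at the joint
#' (probability `p_direct`) or binds 3' of it and translocates into it.
#' Conditional outcome distributions (each summing to 1):
#' direct -> stall / disrupt (joint co-moves with the motor) / other;
#' translocation -> stall / bypass / other.
#'
#' @param p_direct Probability of direct recruitment at the joint.
#' @param direct_outcomes Named probabilities `c(stall=, disrupt=, other=)`.
#' @param transloc_outcomes Named probabilities `c(stall=, bypass=, other=)`.
#' @param heteroduplex_position Joint position, nt from the 5' end.
#' @return A `collision_model` object.
#' @export
collision_model <- function(p_direct,
                            direct_outcomes = c(stall = 1, disrupt = 0, other = 0),
                            transloc_outcomes = c(stall = 1, bypass = 0, other = 0),
                            heteroduplex_position = 20000) {
  check_probability(p_direct, "p_direct")
  check_positive(heteroduplex_position, "heteroduplex_position")
  for (nm in c("stall", "disrupt", "other")) check_probability(direct_outcomes[[nm]], paste0("direct_outcomes$", nm))
  for (nm in c("stall", "bypass", "other")) check_probability(transloc_outcomes[[nm]], paste0("transloc_outcomes$", nm))
  if (abs(sum(direct_outcomes) - 1) > 1e-8 || abs(sum(transloc_outcomes) - 1) > 1e-8) {
    abort_invalid("Conditional outcome probabilities must each sum to 1.")
  }
  structure(
    list(
      p_direct = p_direct,
      direct_outcomes = direct_outcomes[c("stall", "disrupt", "other")],
      transloc_outcomes = transloc_outcomes[c("stall", "bypass", "other")],
      heteroduplex_position = heteroduplex_position
    ),
    class = "collision_model"
  )
}
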