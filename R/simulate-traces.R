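new_intensity_trace <- function(time_s, intensity, ...) {
  structure(
    tibble(time_s = time_s, intensity = intensity),
    class = c("intensity_trace", class(tibble())),
    ...
  )
}

#' Simulate a stepwise photobleaching trace
#'
#' A punctum containing `n_fluorophores` GFPs is illuminated continuously;
#' each fluorophore bleaches after an i.i.d. exponential waiting time with
#' rate `bleach_rate`, so the intensity is `step_height` times the number of
#' surviving fluorophores plus Gaussian camera noise.
#'
#' @param n_fluorophores Number of fluorophores (>= 0).
#' @param step_height Intensity contributed by one fluorophore, a.u.
#' @param bleach_rate Per-fluorophore bleaching rate, 1/s.
#' @param noise_sd Gaussian noise SD, a.u. (>= 0).
#' @param duration Trace duration, s.
#' @param dt Sampling interval, s.
#' @param seed Optional RNG seed.
#' @return An `intensity_trace` tibble (`time_s`, `intensity`) with
#'   attributes `n_fluorophores` and `bleach_times` (ground truth).
#' @export
simulate_photobleach_trace <- function(n_fluorophores, step_height = 1,
                                       bleach_rate = 0.05, noise_sd = 0,
                                       duration = 200, dt = 0.5, seed = NULL) {
  if (n_fluorophores < 0) abort_invalid("`n_fluorophores` must be >= 0.")
  check_nonnegative(noise_sd, "noise_sd")
  check_positive(step_height, "step_height")
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  set_seed_if(seed)
  times <- seq(0, duration, by = dt)
  bleach_times <- if (n_fluorophores > 0 && bleach_rate > 0) {
    sort(stats::rexp(n_fluorophores, bleach_rate))
  } else if (n_fluorophores > 0) {
    rep(Inf, n_fluorophores)
  } else {
    numeric(0)
  }
  surviving <- vapply(times, function(t) sum(bleach_times > t), numeric(1))
  intensity <- step_height * surviving
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(length(times), 0, noise_sd)
  new_intensity_trace(times, intensity,
                      n_fluorophores = as.integer(n_fluorophores),
                      bleach_times = bleach_times, seed = seed)
}

#' Simulate an exponential exchange curve
#'
#' Generates the normalised coat-fluorescence trace of recombinase filament
#' assembly (`decay`: `I = A e^{-kt}`, coat protein displaced) or
#' disassembly (`recovery`: `I = A (1 - e^{-kt})`, coat protein rebinding),
#' plus Gaussian noise.
#'
#' @param model `"decay"` or `"recovery"`.
#' @param A Amplitude (> 0).
#' @param k Rate constant, 1/s (>= 0).
#' @param noise_sd Gaussian noise SD.
#' @param duration Duration, s.
#' @param dt Sampling interval, s (> 0).
#' @param seed Optional RNG seed.
#' @return An `intensity_trace` tibble with attributes `model`, `A`, `k`.
#' @export
simulate_exchange_curve <- function(model = c("decay", "recovery"), A = 1,
                                    k = 1e-3, noise_sd = 0, duration = 1200,
                                    dt = 10, seed = NULL) {
  model <- match.arg(model)
  check_positive(A, "A")
  check_nonnegative(k, "k")
  check_nonnegative(noise_sd, "noise_sd")
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  set_seed_if(seed)
  times <- seq(0, duration, by = dt)
  mu <- if (model == "decay") A * exp(-k * times) else A * (1 - exp(-k * times))
  y <- if (noise_sd > 0) mu + stats::rnorm(length(times), 0, noise_sd) else mu
  new_intensity_trace(times, y, model = model, A = A, k = k, seed = seed)
}

#' Simulate a biolayer interferometry sensorgram
#'
#' Builds a five-step sensorgram (baseline, DNA loading, wash, protein
#' association, dissociation) in nm of optical thickness. Loading and
#' association phases rise as saturating exponentials; the dissociation
#' phase decays as the sum of a fast and a slow exponential of the signal
#' at the start of dissociation (the fast component models motor-dependent
#' recombinase removal, the slow component peptide-only destabilisation).
#'
#' @param phase_schedule Tibble/data frame with `label` and `start_s`
#'   columns, strictly increasing start times. Defaults to the standard
#'   five-step protocol (baseline 0, loading 30, wash 150, association 180,
#'   dissociation 450 s).
#' @param dissociation List with `fast_amp`, `fast_k`, `slow_amp`, `slow_k`.
#'   Amplitudes are fractions of the signal at the start of dissociation
#'   (non-negative; any remainder persists as a plateau).
#' @param duration Total duration, s.
#' @param dt Sampling interval, s.
#' @param noise_sd Gaussian noise SD, nm.
#' @param loading_amp,assoc_amp,loading_k,assoc_k Saturating-exponential
#'   parameters of the loading and association phases.
#' @param seed Optional RNG seed.
#' @return A `sensorgram` object: tibble (`time_s`, `signal_nm`, `phase`)
#'   with the schedule in `attr(, "schedule")`.
#' @export
simulate_bli_sensorgram <- function(phase_schedule = NULL,
                                    dissociation = list(fast_amp = 0.4, fast_k = 0.05,
                                                        slow_amp = 0.6, slow_k = 0.002),
                                    duration = 700, dt = 0.5, noise_sd = 0,
                                    loading_amp = 0.8, loading_k = 0.05,
                                    assoc_amp = 4, assoc_k = 0.02, seed = NULL) {
  if (is.null(phase_schedule)) {
    phase_schedule <- tibble(
      label = c("baseline", "loading", "wash", "association", "dissociation"),
      start_s = c(0, 30, 150, 180, 450)
    )
  }
  phase_schedule <- as_tibble(phase_schedule)
  if (any(diff(phase_schedule$start_s) <= 0)) {
    abort_invalid("Phase start times must be strictly increasing.")
  }
  for (nm in c("fast_amp", "slow_amp")) {
    if (dissociation[[nm]] < 0) abort_invalid("Dissociation amplitudes must be non-negative.")
  }
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  set_seed_if(seed)

  times <- seq(0, duration, by = dt)
  sig <- numeric(length(times))
  level <- 0
  for (i in seq_len(nrow(phase_schedule))) {
    lab <- phase_schedule$label[i]
    t0 <- phase_schedule$start_s[i]
    t1 <- if (i < nrow(phase_schedule)) phase_schedule$start_s[i + 1L] else duration + dt
    in_phase <- times >= t0 & times < t1
    tt <- times[in_phase] - t0
    sig[in_phase] <- switch(lab,
      baseline = level,
      loading = level + loading_amp * (1 - exp(-loading_k * tt)),
      wash = level,
      association = level + assoc_amp * (1 - exp(-assoc_k * tt)),
      dissociation = {
        fa <- dissociation$fast_amp; sa <- dissociation$slow_amp
        rest <- max(0, 1 - fa - sa)
        level * (fa * exp(-dissociation$fast_k * tt) +
                 sa * exp(-dissociation$slow_k * tt) + rest)
      },
      level
    )
    level <- sig[max(which(in_phase))]
  }
  if (noise_sd > 0) sig <- sig + stats::rnorm(length(times), 0, noise_sd)
  out <- tibble(time_s = times, signal_nm = sig)
  segment_phases(out, phase_schedule)
}

#' Simulate DNA-end fluorescence traces for focus scoring
#'
#' Emulates the end-bound unwinding assay: each DNA end is watched as a
#' short kymograph strip; positive ends develop a dim stationary
#' fluorescent-coat focus (appearing around `appearance_s`) at the end
#' position, negative ends show background noise only.
#'
#' @param n_positive,n_negative Number of ends with/without a focus.
#' @param snr Peak amplitude of the focus in units of the noise SD.
#' @param n_frames Frames per trace.
#' @param n_px Pixels per trace strip (focus at the centre).
#' @param appearance_s Mean focus appearance time, s.
#' @param seed RNG seed.
#' @return List of [as_kymograph()] strips with attribute `truth`
#'   (logical vector, focus present).
#' @export
simulate_end_traces <- function(n_positive, n_negative, snr = 6,
                                n_frames = 120L, n_px = 21L,
                                appearance_s = 360, seed = NULL) {
  if (n_positive < 0 || n_negative < 0) abort_invalid("Counts must be >= 0.")
  set_seed_if(seed)
  imaging <- imaging_model(n_pixels = n_px, photon_gain = 0, read_noise = 1, brightness = 100)
  n <- n_positive + n_negative
  truth <- rep(c(TRUE, FALSE), c(n_positive, n_negative))
  px <- seq_len(n_px) - 1L
  centre <- (n_px - 1L) / 2
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    mat <- matrix(stats::rnorm(n_frames * n_px), n_frames, n_px)
    if (truth[i]) {
      f0 <- max(1L, round(stats::rnorm(1, appearance_s / imaging$frame_interval, 3)))
      prof <- snr * exp(-(px - centre)^2 / (2 * imaging$psf_sigma^2))
      for (f in f0:n_frames) mat[f, ] <- mat[f, ] + prof
    }
    traces[[i]] <- as_kymograph(mat, imaging, channel = "coat")
  }
  structure(traces, truth = truth, seed = seed)
}
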