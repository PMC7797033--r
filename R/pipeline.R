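#' Track all translocation events in a rendered single-event kymograph
#'
#' Runs the tracking route appropriate for the experiment: `front` detects
#' the exchange/clearing front of the fluorescent coat, `puncta` follows
#' the labeled motor's diffraction-limited spot. Returns quantified events
#' from [segment_translocation()].
#'
#' @param kymos Named list of kymographs from [render_kymograph()].
#' @param track `"front"` or `"puncta"`.
#' @param mode Coat mode for front detection (`"clearing"`/`"exchange"`).
#' @param min_snr Punctum detection gate for the `puncta` route; the motor
#'   channel has near-zero background, so a strict gate rejects camera-noise
#'   detections without touching the bright motor spot.
#' @param ... Passed to [segment_translocation()].
#' @return Event tibble (zero or more rows).
#' @export
track_translocation <- function(kymos, track = c("front", "puncta"),
                                mode = "exchange", min_snr = 5, ...) {
  track <- match.arg(track)
  if (track == "front") {
    ch <- if (mode == "clearing") "coat" else "trail"
    kymo <- kymos[[ch]]
    if (is.null(kymo)) abort_invalid(sprintf("No '%s' channel in `kymos`.", ch))
    fronts <- detect_front(kymo, mode = mode)
    traj <- fronts |>
      filter(!.data$missing) |>
      select("frame", "time_s", position_px = "front_px")
    if (nrow(traj) == 0L) return(segment_translocation(traj, kymo$imaging, ...))
    origin <- stats::median(fronts$origin_px[!fronts$missing], na.rm = TRUE)
    segment_translocation(traj, kymo$imaging, origin_px = origin, ...)
  } else {
    kymo <- kymos[["motor"]]
    if (is.null(kymo)) abort_invalid("No 'motor' channel in `kymos`.")
    det <- track_puncta(kymo, min_snr = min_snr)
    if (nrow(det) == 0L) {
      return(segment_translocation(tibble(time_s = numeric(), position_px = numeric()),
                                   kymo$imaging, ...))
    }
    main <- det |> dplyr::count(.data$track_id) |> arrange(dplyr::desc(.data$n)) |> dplyr::slice(1L)
    traj <- det |> filter(.data$track_id == main$track_id)
    segment_translocation(traj, kymo$imaging, appearance_correction = TRUE, ...)
  }
}

#' Run the full simulate -> render -> track -> fit pipeline for a preset
#'
#' Simulates the preset's number of binding events (each on its own ssDNA
#' molecule, the single-motor regime of a dilute injection), renders each
#' molecule's kymograph with camera noise, tracks fronts or motor puncta,
#' segments translocation events, and fits the velocity distribution
#' (15 nt/s-binned Gaussian) and the distance survival curve (exponential
#' half-life with bootstrap CI). Censored events are kept for velocity but
#' excluded from the survival fit; the minimum-displacement detection
#' threshold is passed to the survival fit as its left-truncation offset.
#'
#' @param preset A preset name (see [curtain_preset()]) or preset list.
#' @param seed RNG seed controlling the whole run.
#' @param noise Render with camera noise? `FALSE` gives the noise-free
#'   oracle configuration.
#' @param n_boot Bootstrap resamples for the processivity CI.
#' @return An `experiment_fit` list: `preset`, `truth_events`, `events`,
#'   `velocity_fit`, `survival_fit`, `seed`.
#' @export
analyze_preset_experiment <- function(preset, seed = 1, noise = TRUE,
                                      n_boot = 1000) {
  if (is.character(preset)) preset <- curtain_preset(preset)
  imaging <- preset$imaging
  if (!noise) imaging <- noise_free(imaging)

  truth <- simulate_translocation_events(
    preset$motor, preset$ssDNA_length, preset$duration,
    seed = seed, n_events = preset$n_events, bind_window = preset$bind_window
  )

  events <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    one <- truth[i, ]
    attr(one, "motor") <- attr(truth, "motor")
    attr(one, "ssDNA_length") <- attr(truth, "ssDNA_length")
    attr(one, "duration") <- attr(truth, "duration")
    class(one) <- class(truth)
    kymos <- render_kymograph(one, imaging)
    ev <- track_translocation(kymos, track = preset$track,
                              mode = preset$motor$mode)
    if (nrow(ev)) ev$truth_event_id <- one$event_id
    ev
  })

  if (nrow(events) < 10L) {
    abort_insufficient("Fewer than 10 events were recovered by tracking.")
  }
  vfit <- fit_velocity_distribution(events$velocity_nt_s)
  sfit <- fit_processivity(
    events$distance_nt[!events$censored],
    n_boot = n_boot, seed = seed + 1L, d_min = 1450
  )
  structure(
    list(preset = preset, truth_events = truth, events = events,
         velocity_fit = vfit, survival_fit = sfit, seed = seed),
    class = "experiment_fit"
  )
}

#' @export
print.experiment_fit <- function(x, ...) {
  cat(sprintf(
    "<experiment_fit> preset %s: v = %.1f +/- %.1f nt/s (N = %d), half-life = %.0f nt (95%% CI %.0f-%.0f)\n",
    x$preset$name %||% "<custom>", x$velocity_fit$mu, x$velocity_fit$sigma,
    x$velocity_fit$n, x$survival_fit$half_life, x$survival_fit$ci[1], x$survival_fit$ci[2]
  ))
  invisible(x)
}
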