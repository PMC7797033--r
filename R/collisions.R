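# Render channels from per-frame punctum positions (px; NA = absent).
render_puncta_channel <- function(positions_px, imaging) {
  nf <- length(positions_px); np <- imaging$n_pixels
  mu <- matrix(0, nf, np)
  ctr <- (0:(np - 1L)) + 0.5
  sig <- max(imaging$psf_sigma, 1e-6)
  for (f in which(!is.na(positions_px))) {
    mu[f, ] <- imaging$brightness * exp(-(ctr - positions_px[f])^2 / (2 * sig^2))
  }
  as_kymograph(apply_camera_noise(mu, imaging), imaging)
}

sample_collision_category <- function(collision) {
  pathway <- if (stats::runif(1) < collision$p_direct) "direct" else "translocation"
  probs <- if (pathway == "direct") collision$direct_outcomes else collision$transloc_outcomes
  outcome <- sample(names(probs), 1L, prob = probs)
  list(pathway = pathway, outcome = outcome)
}

#' Sample encounter categories without rendering
#'
#' Draws pathway/outcome labels from a [collision_model()], for checking
#' the sampler's calibration at large n without the cost of rendering.
#'
#' @param collision A [collision_model()].
#' @param n Number of draws.
#' @param seed Optional RNG seed.
#' @return Tibble with `pathway` and `outcome`, one row per draw.
#' @export
simulate_collision_outcomes <- function(collision, n, seed = NULL) {
  stopifnot(inherits(collision, "collision_model"))
  set_seed_if(seed)
  purrr::map_dfr(seq_len(n), function(i) {
    ct <- sample_collision_category(collision)
    tibble(pathway = ct$pathway, outcome = ct$outcome)
  })
}

#' Simulate a motor/heteroduplex collision movie
#'
#' Renders a two-channel kymograph of one encounter between a translocating
#' motor and a stationary heteroduplex DNA joint. The joint channel carries
#' a static punctum at the joint; the motor channel realises the drawn (or
#' requested) pathway and outcome: direct recruitment places the motor at
#' the joint from its appearance, the translocation pathway starts it 3' of
#' the joint and walks it in. Outcomes: `stall` (motor stops at the joint),
#' `disrupt` (direct only; the joint punctum co-moves with the motor),
#' `bypass` (translocation only; the motor passes while the joint persists),
#' `other` (motor leaves the joint behind, or the joint is released at
#' contact).
#'
#' @param collision A [collision_model()].
#' @param motor A [motor_model()] (velocity distribution).
#' @param imaging An [imaging_model()].
#' @param seed Optional RNG seed.
#' @param pathway,outcome Force a category instead of sampling it.
#' @param duration Movie duration, s.
#' @return List with `kymographs` (named list: `motor`, `joint`) and
#'   `truth` (one-row tibble: `pathway`, `outcome`, `joint_position_nt`,
#'   `velocity_nt_s`, `appear_s`, `contact_s`).
#' @export
simulate_collision_movie <- function(collision, motor, imaging, seed = NULL,
                                     pathway = NULL, outcome = NULL,
                                     duration = 600) {
  stopifnot(inherits(collision, "collision_model"), inherits(motor, "motor_model"),
            inherits(imaging, "imaging_model"))
  if (collision$heteroduplex_position >= imaging$n_pixels * imaging$nt_per_pixel) {
    abort_invalid("`heteroduplex_position` lies outside the imaged lattice.")
  }
  set_seed_if(seed)
  if (is.null(pathway) || is.null(outcome)) {
    cat_ <- sample_collision_category(collision)
    pathway <- pathway %||% cat_$pathway
    outcome <- outcome %||% cat_$outcome
  }
  pathway <- match.arg(pathway, c("direct", "translocation"))
  outcome <- match.arg(outcome, c("stall", "disrupt", "bypass", "other"))

  npp <- imaging$nt_per_pixel
  times <- seq(0, duration, by = imaging$frame_interval)
  nf <- length(times)
  joint_px <- collision$heteroduplex_position / npp
  v_px <- rtnorm_pos(1L, motor$velocity_mean, motor$velocity_sd) / npp  # px/s
  appear_s <- stats::runif(1, 2, 8) * imaging$frame_interval

  motor_pos <- rep(NA_real_, nf)
  joint_pos <- rep(joint_px, nf)
  gap_px <- stats::runif(1, 8, 15)
  dwell_s <- 3 * imaging$frame_interval

  if (pathway == "direct") {
    contact_s <- appear_s
    for (f in which(times >= appear_s)) {
      t <- times[f]
      motor_pos[f] <- switch(outcome,
        stall = joint_px,
        disrupt = joint_px - v_px * max(0, t - appear_s - dwell_s),
        other = joint_px - v_px * max(0, t - appear_s - dwell_s),
        bypass = abort_invalid("`bypass` is only defined for the translocation pathway.")
      )
    }
    if (outcome == "disrupt") joint_pos <- ifelse(is.na(motor_pos), joint_px, motor_pos)
  } else {
    if (outcome == "disrupt") {
      abort_invalid("`disrupt` is only defined for the direct pathway.")
    }
    start_px <- joint_px + gap_px
    contact_s <- appear_s + gap_px / v_px
    for (f in which(times >= appear_s)) {
      t <- times[f]
      p <- start_px - v_px * (t - appear_s)
      motor_pos[f] <- switch(outcome,
        stall = max(p, joint_px),
        bypass = p,
        other = p
      )
    }
    if (outcome == "other") joint_pos[times >= contact_s] <- NA_real_
  }
  motor_pos <- pmax(motor_pos, 0)

  kymo_motor <- render_puncta_channel(motor_pos, imaging)
  kymo_motor$channel <- "motor"
  kymo_joint <- render_puncta_channel(joint_pos, imaging)
  kymo_joint$channel <- "joint"

  list(
    kymographs = list(motor = kymo_motor, joint = kymo_joint),
    truth = tibble(
      pathway = pathway, outcome = outcome,
      joint_position_nt = collision$heteroduplex_position,
      velocity_nt_s = v_px * npp, appear_s = appear_s, contact_s = contact_s
    )
  )
}

#' Simulate a cohort of collision movies
#'
#' Either samples categories from a [collision_model()] (`n` movies) or
#' realises an exact category count table (`counts`), as used for fixture
#' cohorts whose tallies must match a published table.
#'
#' @param collision A [collision_model()].
#' @param motor,imaging Models passed to [simulate_collision_movie()].
#' @param n Number of movies to sample (ignored when `counts` given).
#' @param counts Optional tibble `pathway`, `outcome`, `n` of exact counts.
#' @param seed RNG seed.
#' @param duration Movie duration, s.
#' @return List with `movies` (list) and `truth` (tibble, one row each).
#' @export
simulate_collision_cohort <- function(collision, motor, imaging, n = NULL,
                                      counts = NULL, seed = NULL,
                                      duration = 600) {
  set_seed_if(seed)
  if (is.null(counts)) {
    stopifnot(!is.null(n))
    cats <- purrr::map(seq_len(n), ~ sample_collision_category(collision))
  } else {
    counts <- as_tibble(counts)
    cats <- purrr::pmap(counts, function(pathway, outcome, n) {
      replicate(n, list(pathway = pathway, outcome = outcome), simplify = FALSE)
    }) |> purrr::flatten()
  }
  movies <- purrr::map(cats, function(ct) {
    simulate_collision_movie(collision, motor, imaging,
                             pathway = ct$pathway, outcome = ct$outcome,
                             duration = duration)
  })
  truth <- purrr::map_dfr(movies, "truth")
  truth$movie_id <- seq_len(nrow(truth))
  list(movies = movies, truth = truth)
}

#' Locate the heteroduplex joint in the joint channel
#'
#' The joint is the stationary punctum in the second channel; its position
#' is the time-median of the tracked centroid over the frames before any
#' contact. Zero stationary puncta raise a no-joint error; two or more
#' raise an ambiguity error.
#'
#' @param kymo Joint-channel [as_kymograph()].
#' @param min_snr Punctum detection gate (robust SDs above background); the
#'   joint fluorophore is far brighter than camera noise, so a strict gate
#'   costs nothing and keeps chance noise tracks out.
#' @param min_frames Minimum track length to consider (the joint persists
#'   for most of the movie).
#' @return List with `position_px` and `position_nt`.
#' @export
locate_joint <- function(kymo, min_snr = 5, min_frames = 8L) {
  det <- track_puncta(kymo, min_snr = min_snr)
  if (nrow(det) == 0L) abort("No joint punctum found.", class = "curtainr_no_joint")
  # stationarity is assessed on the earliest detections only, so a joint
  # that is later dragged away by the motor still registers
  tracks <- det |>
    group_by(.data$track_id) |>
    summarise(
      n = dplyr::n(),
      pos = stats::median(utils::head(.data$position_px, min_frames)),
      spread = stats::sd(utils::head(.data$position_px, min_frames)),
      .groups = "drop"
    ) |>
    filter(.data$n >= min_frames, is.na(.data$spread) | .data$spread < 1.5)
  if (nrow(tracks) == 0L) abort("No stationary joint punctum found.", class = "curtainr_no_joint")
  if (nrow(tracks) > 1L && diff(range(tracks$pos)) > 2) {
    abort("Multiple stationary puncta: joint position ambiguous.",
          class = "curtainr_ambiguous_joint")
  }
  best <- tracks |> arrange(dplyr::desc(.data$n)) |> dplyr::slice(1L)
  list(position_px = best$pos, position_nt = px_to_nt(best$pos, kymo$imaging))
}

#' Classify one motor/heteroduplex encounter
#'
#' Kinematic classification of an encounter from the motor trajectory, the
#' joint position and the joint trajectory. Pathway: `direct` when the
#' motor first appears within the colocalisation gate of the joint, else
#' `translocation`. Outcomes: `stall` when the motor moves less than the
#' motion gate after contact; `disrupt` (direct) when the joint punctum
#' co-moves with the motor (displacement above the motion gate and
#' position correlation above `corr_gate`); `bypass` (translocation) when
#' the motor passes the joint by more than the motion gate while the joint
#' persists in place; anything else is `other`. Trajectories with fewer
#' than `min_post_frames` points after contact are `indeterminate` and
#' excluded from tallies.
#'
#' @param motor_traj Tibble `frame`, `time_s`, `position_px` (one track).
#' @param joint_position_px Joint position, pixels ([locate_joint()]).
#' @param joint_traj Joint-channel track (may lose the punctum over time).
#' @param imaging An [imaging_model()].
#' @param coloc_gate_px Colocalisation gate (default 1 px, the optical
#'   resolution).
#' @param motion_gate_px Motion gate (default 2 px over >= 3 frames).
#' @param min_post_frames Minimum post-contact frames to assess motion.
#' @param corr_gate Position-correlation gate for `disrupt`.
#' @return One-row tibble: `pathway`, `outcome`, `contact_s`,
#'   `coloc_dist_px`, `indeterminate`.
#' @export
classify_encounter <- function(motor_traj, joint_position_px, joint_traj,
                               imaging, coloc_gate_px = 1, motion_gate_px = 2,
                               min_post_frames = 3L, corr_gate = 0.8) {
  mt <- as_tibble(motor_traj) |> filter(!is.na(.data$position_px)) |> arrange(.data$frame)
  jt <- as_tibble(joint_traj) |> filter(!is.na(.data$position_px)) |> arrange(.data$frame)
  if (nrow(mt) == 0L) abort_insufficient("Empty motor trajectory.")

  first_dist <- abs(mt$position_px[1L] - joint_position_px)
  pathway <- if (first_dist <= coloc_gate_px) "direct" else "translocation"

  contact_idx <- which(abs(mt$position_px - joint_position_px) <= coloc_gate_px)[1L]
  out_row <- function(outcome, contact_s, indet = FALSE) {
    tibble(pathway = pathway, outcome = outcome,
           contact_s = contact_s, coloc_dist_px = first_dist,
           indeterminate = indet)
  }
  if (is.na(contact_idx)) {
    # never reached the joint: no encounter to classify
    return(out_row(NA_character_, NA_real_, indet = TRUE))
  }
  contact_frame <- mt$frame[contact_idx]
  post <- mt[contact_idx:nrow(mt), ]
  if (nrow(post) < min_post_frames) {
    return(out_row(NA_character_, mt$time_s[contact_idx], indet = TRUE))
  }

  motor_disp <- abs(post$position_px[nrow(post)] - post$position_px[1L])
  jpost <- jt |> filter(.data$frame >= contact_frame)
  joint_persists <- nrow(jpost) >= min_post_frames
  joint_disp <- if (nrow(jpost) >= 2L) {
    abs(jpost$position_px[nrow(jpost)] - jpost$position_px[1L])
  } else 0

  outcome <- "other"
  if (motor_disp < motion_gate_px) {
    outcome <- "stall"
  } else if (pathway == "direct" && joint_disp > motion_gate_px) {
    common <- dplyr::inner_join(
      post |> select("frame", mpos = "position_px"),
      jpost |> select("frame", jpos = "position_px"),
      by = "frame"
    )
    if (nrow(common) >= 3L && stats::sd(common$mpos) > 0 && stats::sd(common$jpos) > 0 &&
        stats::cor(common$mpos, common$jpos) > corr_gate) {
      outcome <- "disrupt"
    }
  } else if (pathway == "translocation" &&
             post$position_px[nrow(post)] < joint_position_px - motion_gate_px &&
             joint_persists && joint_disp <= motion_gate_px) {
    outcome <- "bypass"
  }
  out_row(outcome, mt$time_s[contact_idx])
}

#' Classify a rendered collision movie
#'
#' Convenience wrapper: locates the joint, tracks both channels and runs
#' [classify_encounter()] on the longest motor track.
#'
#' @param movie Output of [simulate_collision_movie()] (or a named list of
#'   `motor`/`joint` kymographs).
#' @param ... Gates passed on to [classify_encounter()].
#' @param min_snr Punctum detection gate.
#' @return One-row tibble as for [classify_encounter()].
#' @export
classify_collision_movie <- function(movie, ..., min_snr = 5) {
  kymos <- if (!is.null(movie$kymographs)) movie$kymographs else movie
  joint <- locate_joint(kymos$joint, min_snr = min_snr)
  motor_det <- track_puncta(kymos$motor, min_snr = min_snr)
  if (nrow(motor_det) == 0L) abort_insufficient("No motor punctum detected.")
  main <- motor_det |> dplyr::count(.data$track_id) |> arrange(dplyr::desc(.data$n)) |> dplyr::slice(1L)
  motor_traj <- motor_det |> filter(.data$track_id == main$track_id)
  joint_traj <- track_puncta(kymos$joint, min_snr = min_snr)
  classify_encounter(motor_traj, joint$position_px, joint_traj,
                     kymos$motor$imaging, ...)
}

#' Tally encounter pathways and conditional outcomes
#'
#' @param events Tibble of classified encounters (`pathway`, `outcome`);
#'   indeterminate rows are dropped with a message.
#' @return Tibble with `level` (`"pathway"` or `"outcome"`), `pathway`,
#'   `outcome`, `n`, `total`, `percent`. Pathway percentages are of all
#'   events; outcome percentages are conditional within their pathway.
#' @export
tally_outcomes <- function(events) {
  ev <- as_tibble(events)
  if ("indeterminate" %in% names(ev)) {
    n_drop <- sum(ev$indeterminate)
    if (n_drop > 0) message(n_drop, " indeterminate event(s) excluded from tallies.")
    ev <- ev |> filter(!.data$indeterminate)
  }
  if (nrow(ev) == 0L) abort_insufficient("No classifiable events.")
  total <- nrow(ev)
  path_tab <- ev |>
    dplyr::count(.data$pathway) |>
    mutate(level = "pathway", outcome = NA_character_, total = total,
           percent = 100 * .data$n / total)
  out_tab <- ev |>
    dplyr::count(.data$pathway, .data$outcome) |>
    group_by(.data$pathway) |>
    mutate(level = "outcome", total = sum(.data$n),
           percent = 100 * .data$n / .data$total) |>
    ungroup()
  bind_rows(path_tab, out_tab) |>
    select("level", "pathway", "outcome", "n", "total", "percent")
}

#' Score DNA-end traces for the presence of a fluorescent focus
#'
#' Runs the punctum detector on each end-trace strip and scores an end
#' positive when a punctum is detected in at least `min_frames` frames.
#'
#' A focus is scored present when a track is detected in at least
#' `min_frames` frames and stays put (positional SD at most `max_wander_px`):
#' real end-bound foci are stationary and persistent, while chance noise
#' tracks are short and wander across the linking gate.
#'
#' @param traces List of [as_kymograph()] strips ([simulate_end_traces()]).
#' @param min_snr Detection gate (robust SDs above background).
#' @param min_frames Minimum number of frames with a detection.
#' @param max_wander_px Maximum positional SD of the track, pixels.
#' @return Tibble with `trace_id`, `focus_detected`; summary in
#'   `attr(, "summary")` (`n_positive`, `total`, `percent`).
#' @export
score_end_foci <- function(traces, min_snr = 4, min_frames = 6L,
                           max_wander_px = 1.5) {
  if (length(traces) == 0L) abort_insufficient("No end traces supplied.")
  detected <- vapply(traces, function(k) {
    det <- track_puncta(k, min_snr = min_snr)
    if (nrow(det) == 0L) return(FALSE)
    any(vapply(split(det, det$track_id), function(d) {
      nrow(d) >= min_frames && stats::sd(d$position_px) <= max_wander_px
    }, logical(1)))
  }, logical(1))
  out <- tibble(trace_id = seq_along(traces), focus_detected = detected)
  structure(out, summary = list(
    n_positive = sum(detected), total = length(detected),
    percent = 100 * mean(detected)
  ))
}
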