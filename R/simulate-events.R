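#' Simulate motor binding and translocation events on a long ssDNA molecule
#'
#' Motors bind at Poisson-distributed times (uniform within `bind_window`)
#' and uniformly distributed positions along the ssDNA, then translocate
#' 3'->5' (toward coordinate 0) at a per-molecule velocity drawn from a
#' Gaussian truncated at zero. The run-length draw is exponential with scale
#' `processivity_halflife / log(2)`; the realised run ends at the minimum of
#' the draw, the distance to the 5' end, and the distance coverable before
#' the movie ends, with `censored` set in the latter two cases.
#'
#' @param motor A [motor_model()].
#' @param ssDNA_length Length of the ssDNA lattice, nt.
#' @param duration Movie duration, s.
#' @param seed Optional RNG seed for reproducible draws.
#' @param n_events If given, simulate exactly this many binding events
#'   (bind times uniform on `[0, bind_window]`); otherwise the event count is
#'   Poisson with rate `binding_rate * (ssDNA_length/1000) * duration`.
#' @param bind_window Width of the binding window, s. Defaults to `duration`.
#'   Figure presets use a short window to emulate a bolus protein injection.
#'
#' @return A `truth_log` tibble with one row per event: `event_id`,
#'   `bind_time_s`, `bind_position_nt`, `velocity_nt_s`, `run_length_nt`
#'   (the uncensored draw), `distance_nt` (realised), `end_time_s`,
#'   `censored`, `censor_reason` (`"none"`, `"ssDNA_end"`, `"movie_end"`).
#'   Attributes `motor`, `ssDNA_length`, `duration`, `seed` carry the
#'   generating configuration.
#' @export
simulate_translocation_events <- function(motor, ssDNA_length, duration,
                                          seed = NULL, n_events = NULL,
                                          bind_window = duration) {
  stopifnot(inherits(motor, "motor_model"))
  check_positive(ssDNA_length, "ssDNA_length")
  check_positive(duration, "duration")
  check_positive(bind_window, "bind_window")
  set_seed_if(seed)

  n <- if (is.null(n_events)) {
    stats::rpois(1L, motor$binding_rate * (ssDNA_length / 1000) * duration)
  } else {
    as.integer(n_events)
  }
  if (n == 0L) {
    out <- tibble(
      event_id = integer(), bind_time_s = double(), bind_position_nt = double(),
      velocity_nt_s = double(), run_length_nt = double(), distance_nt = double(),
      end_time_s = double(), censored = logical(), censor_reason = character()
    )
  } else {
    bind_time <- stats::runif(n, 0, min(bind_window, duration))
    bind_pos <- stats::runif(n, 0, ssDNA_length)
    vel <- rtnorm_pos(n, motor$velocity_mean, motor$velocity_sd)
    run <- stats::rexp(n, rate = log(2) / motor$processivity_halflife)
    max_by_movie <- vel * (duration - bind_time)
    dist <- pmin(run, bind_pos, max_by_movie)
    reason <- dplyr::case_when(
      dist == run ~ "none",
      dist == bind_pos ~ "ssDNA_end",
      TRUE ~ "movie_end"
    )
    out <- tibble(
      event_id = seq_len(n),
      bind_time_s = bind_time,
      bind_position_nt = bind_pos,
      velocity_nt_s = vel,
      run_length_nt = run,
      distance_nt = dist,
      end_time_s = bind_time + ifelse(vel > 0, dist / vel, duration - bind_time),
      censored = reason != "none",
      censor_reason = reason
    )
  }
  structure(out,
    class = c("truth_log", class(out)),
    motor = motor, ssDNA_length = ssDNA_length, duration = duration, seed = seed
  )
}

#' @export
print.truth_log <- function(x, ...) {
  cat(sprintf(
    "<truth_log> %d events on %g nt ssDNA over %g s (%d censored)\n",
    nrow(x), attr(x, "ssDNA_length"), attr(x, "duration"), sum(x$censored)
  ))
  NextMethod()
}

# Motor position (nt) of one truth event at given times; NA before binding,
# held at the stop position after the run ends.
motor_position_nt <- function(event, times) {
  p <- event$bind_position_nt - event$velocity_nt_s * pmax(0, pmin(times, event$end_time_s) - event$bind_time_s)
  p[times < event$bind_time_s] <- NA_real_
  pmax(p, 0)
}
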