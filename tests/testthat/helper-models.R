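# shared fixture builders

steady_motor <- function(v = 60, hl = 7900, mode = "exchange", labeled = FALSE) {
  motor_model(v, 0, hl, mode = mode, motor_labeled = labeled)
}

small_imaging <- function(n_pixels = 70, noise = FALSE) {
  im <- imaging_model(n_pixels = n_pixels)
  if (!noise) im <- noise_free(im) else im
}

# truth motor position (nt) for a one-event log at given times
motor_position_frames <- function(tl, times) {
  run_t <- tl$distance_nt / tl$velocity_nt_s
  pos <- tl$bind_position_nt -
    tl$velocity_nt_s * pmin(pmax(times - tl$bind_time_s, 0), run_t)
  pos[times < tl$bind_time_s] <- NA_real_
  pos
}

# single-event truth log at a controlled position/velocity
one_event_truth <- function(motor, bind_position_nt, velocity_nt_s, distance_nt,
                            bind_time_s = 50, ssDNA_length = 50000,
                            duration = 600) {
  tl <- simulate_translocation_events(motor, ssDNA_length, duration,
                                      seed = 1, n_events = 1)
  tl$bind_time_s <- bind_time_s
  tl$bind_position_nt <- bind_position_nt
  tl$velocity_nt_s <- velocity_nt_s
  tl$run_length_nt <- distance_nt
  tl$distance_nt <- distance_nt
  tl$end_time_s <- bind_time_s + distance_nt / velocity_nt_s
  tl$censored <- FALSE
  tl$censor_reason <- "none"
  tl
}
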