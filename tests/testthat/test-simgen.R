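test_that("deterministic velocity limit gives exact run durations", {
  m <- steady_motor(v = 60)
  tl <- simulate_translocation_events(m, 5e4, 600, seed = 1, n_events = 20)
  expect_true(all(tl$velocity_nt_s == 60))
  expect_equal(tl$end_time_s - tl$bind_time_s, tl$distance_nt / 60)
})

test_that("zero binding rate yields an empty event log", {
  m <- motor_model(60, 10, 7900, binding_rate = 0)
  tl <- simulate_translocation_events(m, 5e4, 600, seed = 1)
  expect_equal(nrow(tl), 0L)
})

test_that("invalid durations and lengths are rejected", {
  m <- steady_motor()
  expect_error(simulate_translocation_events(m, -1, 600), class = "curtainr_invalid_parameter")
  expect_error(simulate_translocation_events(m, 5e4, 0), class = "curtainr_invalid_parameter")
})

test_that("uncensored run lengths follow the exponential run-length law", {
  m <- motor_model(60, 10, 7900, mode = "exchange")
  # long lattice and movie so censoring is negligible and does not distort
  tl <- simulate_translocation_events(m, 5e6, 5e4, seed = 42, n_events = 10000,
                                      bind_window = 100)
  unc <- tl$distance_nt[!tl$censored]
  expect_gt(length(unc), 9500)
  # median of an exponential equals its half-life
  expect_equal(stats::median(unc), 7900, tolerance = 400 / 7900)
  ks <- suppressWarnings(stats::ks.test(unc, "pexp", rate = log(2) / 7900))
  expect_gt(ks$p.value, 0.01)
})

test_that("same seed gives bit-identical events and renders", {
  m <- motor_model(60, 15, 8000, mode = "exchange", motor_labeled = TRUE)
  t1 <- simulate_translocation_events(m, 5e4, 600, seed = 7, n_events = 5)
  t2 <- simulate_translocation_events(m, 5e4, 600, seed = 7, n_events = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  im <- imaging_model(n_pixels = 70)
  k1 <- render_kymograph(t1, im, seed = 3)
  k2 <- render_kymograph(t2, im, seed = 3)
  expect_identical(k1$trail$data, k2$trail$data)
  expect_identical(k1$motor$data, k2$motor$data)
})

test_that("noise-free clearing render puts the front at the truth position", {
  m <- steady_motor(v = 60, mode = "clearing")
  tl <- one_event_truth(m, bind_position_nt = 40000, velocity_nt_s = 60,
                        distance_nt = 18000)
  k <- render_kymograph(tl, small_imaging())
  fr <- detect_front(k$coat, mode = "clearing")
  ok <- !fr$missing & fr$front_px > 0.5
  truth_px <- motor_position_frames(tl, fr$time_s[ok]) / 725
  expect_true(all(abs(fr$front_px[ok] - truth_px) <= 0.5))
})

test_that("no motors leaves the coat channel constant over time", {
  m <- motor_model(60, 10, 7900, binding_rate = 0, mode = "clearing")
  tl <- simulate_translocation_events(m, 5e4, 300, seed = 1)
  k <- render_kymograph(tl, small_imaging())
  expect_true(all(apply(k$coat$data, 2, function(col) diff(range(col))) == 0))
})

test_that("a motor moving one pixel per frame advances the front 1 px/frame", {
  # 725 nt per 10 s frame = 72.5 nt/s
  m <- steady_motor(v = 72.5, mode = "exchange")
  tl <- one_event_truth(m, bind_position_nt = 43500, velocity_nt_s = 72.5,
                        distance_nt = 29000, bind_time_s = 0)
  k <- render_kymograph(tl, small_imaging())
  fr <- detect_front(k$trail, mode = "exchange", isotonic = FALSE)
  # skip the first frames where the nascent trail is still narrower than
  # the PSF and both edges overlap
  moving <- which(!fr$missing & fr$front_px > 1 &
                    fr$time_s >= 50 & fr$time_s < 29000 / 72.5)
  steps <- diff(fr$front_px[moving])
  expect_equal(mean(steps), -1, tolerance = 0.02)
  expect_true(all(abs(steps + 1) < 0.05))
})

test_that("exchange rendering conserves trail length = motor displacement", {
  m <- steady_motor(v = 60, mode = "exchange")
  tl <- one_event_truth(m, bind_position_nt = 35000, velocity_nt_s = 60,
                        distance_nt = 20000)
  im <- small_imaging()
  k <- render_kymograph(tl, im)
  trail_len <- (rowSums(k$trail$data) - ncol(k$trail$data) * im$baseline) /
    im$brightness * im$nt_per_pixel
  truth_pos <- motor_position_frames(tl, k$trail$frame_times)
  displacement <- ifelse(is.na(truth_pos), 0, tl$bind_position_nt - truth_pos)
  expect_true(all(abs(trail_len - displacement) <= im$nt_per_pixel))
})

test_that("duplicate channel labels are a configuration error", {
  m <- steady_motor()
  tl <- simulate_translocation_events(m, 5e4, 300, seed = 1, n_events = 1)
  expect_error(render_kymograph(tl, small_imaging(), channels = c("trail", "trail")),
               class = "curtainr_config_error")
})

test_that("photobleach traces step down through the truth bleach times", {
  tr1 <- simulate_photobleach_trace(1, noise_sd = 0, seed = 3)
  vals <- unique(tr1$intensity)
  expect_setequal(vals, c(1, 0))
  expect_equal(sum(diff(tr1$intensity) != 0), 1L)

  tr0 <- simulate_photobleach_trace(0, noise_sd = 0, seed = 3)
  expect_true(all(tr0$intensity == 0))

  expect_error(simulate_photobleach_trace(2, noise_sd = -1),
               class = "curtainr_invalid_parameter")
})

test_that("mean bleach count in a window matches the closed-form survival", {
  # 3 fluorophores, rate 0.05/s, 200 s window: expect 3 * (1 - exp(-10))
  n_steps <- vapply(1:10000, function(i) {
    tr <- simulate_photobleach_trace(3, bleach_rate = 0.05, duration = 200,
                                     dt = 100, seed = i)
    sum(attr(tr, "bleach_times") <= 200)
  }, numeric(1))
  expect_equal(mean(n_steps), 3 * (1 - exp(-10)), tolerance = 0.001 / 3)
})

test_that("exchange curves evaluate the stated exponential identities", {
  dec <- simulate_exchange_curve("decay", A = 1, k = 0.01, duration = 100, dt = 0.1)
  i_half <- which.min(abs(dec$time_s - log(2) / 0.01))
  expect_equal(dec$intensity[i_half], 0.5, tolerance = 2e-3)

  rec <- simulate_exchange_curve("recovery", A = 1, k = 0.01, duration = 100, dt = 1)
  expect_equal(rec$intensity[1], 0)

  dec2 <- simulate_exchange_curve("decay", A = 1, k = 2.7e-3, duration = 1200, dt = 10)
  expect_equal(dec2$intensity[dec2$time_s == 1200], exp(-3.24), tolerance = 1e-12)

  expect_error(simulate_exchange_curve("decay", dt = 0),
               class = "curtainr_invalid_parameter")
})

test_that("sensorgram dissociation realises the stated biexponential", {
  sg <- simulate_bli_sensorgram(
    dissociation = list(fast_amp = 0.6, fast_k = 0.05, slow_amp = 0.4, slow_k = 0.002)
  )
  d <- sg[sg$phase == "dissociation", ]
  s0 <- d$signal_nm[1]
  at100 <- d$signal_nm[abs((d$time_s - d$time_s[1]) - 100) < 1e-9]
  expect_equal(at100 / s0, 0.6 * exp(-5) + 0.4 * exp(-0.2), tolerance = 1e-9)

  flat <- simulate_bli_sensorgram(
    dissociation = list(fast_amp = 0, fast_k = 0.05, slow_amp = 0, slow_k = 0.002)
  )
  df <- flat[flat$phase == "dissociation", ]
  expect_equal(diff(range(df$signal_nm)), 0)

  single <- simulate_bli_sensorgram(
    dissociation = list(fast_amp = 0, fast_k = 0.05, slow_amp = 1, slow_k = 0.002)
  )
  ds <- single[single$phase == "dissociation", ]
  tt <- ds$time_s - ds$time_s[1]
  expect_equal(ds$signal_nm / ds$signal_nm[1], exp(-0.002 * tt), tolerance = 1e-9)

  expect_error(
    simulate_bli_sensorgram(dissociation = list(fast_amp = -1, fast_k = 1,
                                                slow_amp = 0, slow_k = 0.1)),
    class = "curtainr_invalid_parameter"
  )
})

test_that("forced collision categories are honoured and sampling is calibrated", {
  cm <- collision_model(p_direct = 1,
                        direct_outcomes = c(stall = 1, disrupt = 0, other = 0))
  draws <- simulate_collision_outcomes(cm, 50, seed = 1)
  expect_true(all(draws$pathway == "direct" & draws$outcome == "stall"))

  cm2 <- collision_model(p_direct = 0,
                         transloc_outcomes = c(stall = 0, bypass = 1, other = 0))
  mv <- simulate_collision_movie(cm2, steady_motor(), small_imaging(), seed = 2)
  expect_equal(mv$truth$pathway, "translocation")
  expect_equal(mv$truth$outcome, "bypass")
  # bypass motor crosses the joint position
  pos <- apply(mv$kymographs$motor$data, 1, which.max)
  expect_lt(min(pos) - 1, mv$truth$joint_position_nt / 725)

  pre <- collision_preset()
  big <- simulate_collision_outcomes(pre$model, 10000, seed = 9)
  p <- pre$model$p_direct
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(big$pathway == "direct") - p), 3 * se)
})
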