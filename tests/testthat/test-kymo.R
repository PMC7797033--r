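test_that("extract_kymograph slices the ROI line out of a stack", {
  im <- small_imaging(n_pixels = 30)
  stack <- array(5, dim = c(8, 4, 30))
  k <- extract_kymograph(stack, list(row = 2), im)
  expect_equal(dim(k$data), c(8L, 30L))
  expect_true(all(k$data == 5))

  stack[3, 2, ] <- 1:30
  k2 <- extract_kymograph(stack, list(row = 2), im)
  expect_equal(k2$data[3, ], 1:30)

  expect_error(extract_kymograph(stack, list(row = 9), im),
               class = "curtainr_bounds_error")
})

test_that("extracting the rendered stack reproduces the direct kymograph", {
  m <- steady_motor(v = 60, mode = "exchange")
  tl <- one_event_truth(m, 35000, 60, 15000)
  im <- small_imaging()
  k <- render_kymograph(tl, im)$trail
  # build a 3-row stack whose middle row carries the molecule
  stack <- array(0, dim = c(nrow(k$data), 3, ncol(k$data)))
  stack[, 2, ] <- k$data
  k2 <- extract_kymograph(stack, list(row = 2), im, channel = "trail")
  expect_identical(k2$data, k$data)
})

test_that("px_to_nt applies the lattice conversion factor", {
  im <- imaging_model()
  expect_equal(px_to_nt(1, im), 725)
  expect_equal(px_to_nt(0, im), 0)
  expect_equal(px_to_nt(13.1, im), 9497.5)
})

test_that("noise-free front trajectory recovers the truth velocity", {
  m <- steady_motor(v = 60, mode = "clearing")
  tl <- one_event_truth(m, 40000, 60, 20000)
  k <- render_kymograph(tl, small_imaging())
  fr <- detect_front(k$coat, mode = "clearing")
  run <- !fr$missing & fr$time_s > tl$bind_time_s + 20 &
    fr$time_s < tl$end_time_s - 20
  slope <- stats::coef(stats::lm(front_px ~ time_s, data = fr[run, ]))[[2]]
  expect_equal(abs(slope) * 725, 60, tolerance = 1 / 60)
})

test_that("front detection marks coated frames missing and cleared frames at the 5' edge", {
  im <- small_imaging(n_pixels = 40)
  # frame 1 fully coated, frame 2 half cleared, frame 3 fully cleared
  mat <- rbind(rep(100, 40), c(rep(0, 20), rep(100, 20)), rep(0, 40))
  k <- as_kymograph(mat, im, "coat")
  fr <- detect_front(k, mode = "clearing", isotonic = FALSE)
  expect_true(fr$missing[1])
  expect_false(fr$missing[2])
  expect_equal(fr$front_px[3], 0)
})

test_that("detected clearing fronts never retreat after cleanup", {
  m <- motor_model(60, 0, 8000, mode = "clearing")
  tl <- one_event_truth(m, 40000, 60, 20000)
  k <- render_kymograph(tl, imaging_model(n_pixels = 70), seed = 5)
  fr <- detect_front(k$coat, mode = "clearing")
  expect_true(all(diff(fr$front_px[!fr$missing]) <= 1e-9))
})

test_that("puncta tracking follows stationary and moving spots", {
  im <- small_imaging(n_pixels = 50)
  # stationary punctum at continuous position 25 (pixel centres at i + 0.5)
  mat <- matrix(0, 20, 50)
  prof <- 100 * exp(-(((0:49) + 0.5) - 25)^2 / 2)
  for (f in 1:20) mat[f, ] <- prof
  det <- track_puncta(as_kymograph(mat, im))
  expect_equal(length(unique(det$track_id)), 1L)
  expect_true(all(abs(det$position_px - 25) < 0.1))

  # moving punctum at 55 nt/s
  m <- motor_model(55, 0, 8000, mode = "exchange", motor_labeled = TRUE)
  tl <- one_event_truth(m, 30000, 55, 15000, ssDNA_length = 36000)
  k <- render_kymograph(tl, im)
  det2 <- track_puncta(k$motor)
  main <- det2[det2$track_id == 1, ]
  run <- main$time_s > tl$bind_time_s & main$time_s < tl$end_time_s
  slope <- stats::coef(stats::lm(position_px ~ time_s, data = main[run, ]))[[2]]
  expect_equal(abs(slope) * 725, 55, tolerance = 2 / 55)

  # empty kymograph
  empty <- as_kymograph(matrix(0, 10, 50), im)
  expect_equal(nrow(track_puncta(empty)), 0L)
})

test_that("translocation segmentation converts slopes with the lattice factor", {
  im <- imaging_model()
  traj <- tibble::tibble(
    frame = 1:12, time_s = (0:11) * 10,
    position_px = c(50 - (0:9), 40, 40) # 1 px/frame then parked
  )
  ev <- segment_translocation(traj, im)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$velocity_nt_s, 72.5, tolerance = 1e-6)
  expect_equal(ev$distance_nt, 10 * 725, tolerance = 1e-6)
  expect_false(ev$censored)
})

test_that("stationary trajectories produce no event", {
  im <- imaging_model()
  traj <- tibble::tibble(frame = 1:30, time_s = (0:29) * 10,
                         position_px = rep(33, 30))
  expect_equal(nrow(segment_translocation(traj, im)), 0L)
})

test_that("short or small-displacement trajectories are rejected", {
  im <- imaging_model()
  short <- tibble::tibble(frame = 1:2, time_s = c(0, 10), position_px = c(10, 8))
  expect_equal(nrow(segment_translocation(short, im)), 0L)
  tiny <- tibble::tibble(frame = 1:10, time_s = (0:9) * 10,
                         position_px = 10 - (0:9) * 0.1)
  expect_equal(nrow(segment_translocation(tiny, im)), 0L)
})

test_that("events moving away from the 5' end are rejected", {
  im <- imaging_model()
  wrong_way <- tibble::tibble(frame = 1:12, time_s = (0:11) * 10,
                              position_px = c(10 + (0:9), 19, 19))
  expect_equal(nrow(segment_translocation(wrong_way, im)), 0L)
})

test_that("noise-free pipeline recovers each truth event to oracle accuracy", {
  p <- curtain_preset("fig4DE")
  motor <- p$motor
  im <- noise_free(p$imaging)
  set.seed(20)
  checked <- 0L
  for (s in 1:18) {
    tl <- simulate_translocation_events(motor, p$ssDNA_length, p$duration,
                                        seed = 100 + s, n_events = 1,
                                        bind_window = p$bind_window)
    # only events above the declared detection floor (2 px displacement,
    # 3 frames of motion) are expected to be recovered
    if (tl$censored || tl$distance_nt < 2500 ||
        tl$distance_nt / tl$velocity_nt_s < 45) next
    k <- render_kymograph(tl, im)
    ev <- track_translocation(k, track = "front", mode = "exchange")
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$velocity_nt_s, tl$velocity_nt_s,
                 tolerance = 0.02)
    expect_lt(abs(ev$distance_nt - tl$distance_nt), 725)
    checked <- checked + 1L
  }
  expect_gte(checked, 8L)
})

test_that("noise-free front positions match truth within half a pixel", {
  m <- steady_motor(v = 65, mode = "exchange")
  tl <- one_event_truth(m, 38000, 65, 22000)
  k <- render_kymograph(tl, small_imaging())
  fr <- detect_front(k$trail, mode = "exchange")
  ok <- !fr$missing & fr$front_px > 1
  truth_px <- motor_position_frames(tl, fr$time_s[ok]) / 725
  expect_true(all(abs(fr$front_px[ok] - truth_px) <= 0.5))
})
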