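fig3_schedule <- function() {
  tibble::tibble(
    label = c("baseline", "loading", "wash", "association", "dissociation"),
    start_s = c(0, 30, 150, 180, 450)
  )
}

test_that("phase segmentation follows the schedule", {
  sg <- simulate_bli_sensorgram()
  sch <- attr(sg, "schedule")
  for (i in seq_len(nrow(sch))) {
    t0 <- sch$start_s[i]
    t1 <- if (i < nrow(sch)) sch$start_s[i + 1] else Inf
    in_phase <- sg$time_s >= t0 & sg$time_s < t1
    expect_true(all(sg$phase[in_phase] == sch$label[i]))
  }
  expect_equal(sort(unique(sg$phase)), sort(sch$label))
})

test_that("five-step protocol times produce five labeled segments", {
  raw <- tibble::tibble(time_s = seq(0, 700, 0.5), signal_nm = 1)
  sg <- segment_phases(raw, fig3_schedule())
  expect_equal(length(unique(sg$phase)), 5L)
  expect_equal(sg$phase[sg$time_s == 451], "dissociation")
})

test_that("schedules outside the sampled span raise a bounds error", {
  raw <- tibble::tibble(time_s = seq(0, 100, 1), signal_nm = 0)
  expect_error(segment_phases(raw, fig3_schedule()), class = "curtainr_bounds_error")
})

test_that("a sensorgram without a dissociation phase cannot be analysed", {
  raw <- tibble::tibble(time_s = seq(0, 100, 1), signal_nm = 1)
  sg <- segment_phases(raw, tibble::tibble(label = "baseline", start_s = 0))
  ctrl <- sg
  expect_error(normalize_and_subtract(sg, ctrl), class = "curtainr_phase_absent")
})

test_that("normalisation and subtraction behave on identity and flat controls", {
  sg <- simulate_bli_sensorgram(seed = 1)
  diff0 <- normalize_and_subtract(sg, sg)
  expect_true(all(abs(diff0$pct_change) < 1e-12))

  flat <- simulate_bli_sensorgram(
    dissociation = list(fast_amp = 0, fast_k = 1, slow_amp = 0, slow_k = 1)
  )
  test <- simulate_bli_sensorgram(
    dissociation = list(fast_amp = 0, fast_k = 1, slow_amp = 1, slow_k = 0.005)
  )
  d <- normalize_and_subtract(test, flat)
  expect_equal(d$pct_change, 100 * (exp(-0.005 * d$time_s) - 1), tolerance = 1e-9)
})

test_that("mismatched dissociation sampling demands an explicit resample", {
  a <- simulate_bli_sensorgram(duration = 700, dt = 0.5)
  b <- simulate_bli_sensorgram(duration = 700, dt = 1)
  expect_error(normalize_and_subtract(a, b), class = "curtainr_resample_required")
})

test_that("subtraction is linear in offset mode for a flat control", {
  base <- simulate_bli_sensorgram(
    dissociation = list(fast_amp = 0.5, fast_k = 0.05, slow_amp = 0.5, slow_k = 0.002)
  )
  flat <- simulate_bli_sensorgram(
    dissociation = list(fast_amp = 0, fast_k = 1, slow_amp = 0, slow_k = 1)
  )
  zero <- flat
  zero$signal_nm[zero$phase == "dissociation"] <- 1 # flat at a different level
  d1 <- normalize_and_subtract(base, flat, mode = "offset")
  d2 <- normalize_and_subtract(base, zero, mode = "offset")
  expect_equal(d1$pct_change, d2$pct_change, tolerance = 1e-12)
})

test_that("control subtraction isolates the fast component", {
  # test: fast + slow; control: slow only. The difference peaks where the
  # rate gap says it should and a two-term refit recovers the fast rate.
  test <- simulate_bli_sensorgram(
    dissociation = list(fast_amp = 0.4, fast_k = 0.05, slow_amp = 0.6, slow_k = 0.002)
  )
  ctrl <- simulate_bli_sensorgram(
    dissociation = list(fast_amp = 0, fast_k = 0.05, slow_amp = 1, slow_k = 0.002)
  )
  d <- normalize_and_subtract(test, ctrl)
  t_peak <- d$time_s[which.min(d$pct_change)]
  expect_equal(t_peak, log(0.05 / 0.002) / (0.05 - 0.002), tolerance = 0.05)
  fit <- minpack.lm::nlsLM(
    pct_change ~ -a * (exp(-ks * time_s) - exp(-kf * time_s)), data = d,
    start = list(a = 30, ks = 0.003, kf = 0.03),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  expect_equal(coef(fit)[["kf"]], 0.05, tolerance = 0.1)
})

test_that("biphasic fits recover noise-free rates to four significant digits", {
  sg <- simulate_bli_sensorgram(
    dissociation = list(fast_amp = 0.4, fast_k = 0.05, slow_amp = 0.6, slow_k = 0.002),
    duration = 1500
  )
  fit <- fit_biphasic(sg[sg$phase == "dissociation", ])
  expect_false(fit$single)
  expect_equal(fit$fast_k, 0.05, tolerance = 1e-4)
  expect_equal(fit$slow_k, 0.002, tolerance = 1e-4)
  expect_gt(fit$fast_k, fit$slow_k) # ordering invariant
})

test_that("single-exponential input falls back or zeroes the second phase", {
  tr <- tibble::tibble(time_s = seq(0, 600, 2), signal_nm = 3 * exp(-0.01 * seq(0, 600, 2)))
  fit <- suppressWarnings(fit_biphasic(tr))
  expect_true(fit$single || fit$slow_amp < 0.05 * fit$fast_amp ||
                abs(fit$slow_k - fit$fast_k) / fit$fast_k < 0.1)

  flat <- tibble::tibble(time_s = seq(0, 600, 2), signal_nm = 1)
  expect_error(fit_biphasic(flat), class = "curtainr_fit_failure")
})
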