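test_that("large-sample Gaussian fit recovers mean and width", {
  set.seed(1)
  v <- rnorm(1e5, 60, 15)
  fit <- fit_velocity_distribution(v)
  expect_equal(fit$mu, 60, tolerance = 0.2 / 60)
  # the histogram fit inherits a small bin-width inflation of sigma
  # (Sheppard-type, ~ sqrt(sigma^2 + bw^2/12)); assert against that value
  expect_equal(fit$sigma, sqrt(15^2 + 15^2 / 12), tolerance = 0.02)
  expect_equal(sum(fit$bins$count), fit$n)
  # and the fit agrees with the sample moments within 1 nt/s
  expect_lt(abs(fit$mu - mean(v)), 1)
})

test_that("velocity fit rejects degenerate and insufficient input", {
  expect_error(fit_velocity_distribution(rnorm(9, 60, 10)),
               class = "curtainr_insufficient_data")
  expect_error(fit_velocity_distribution(rep(60, 50)),
               class = "curtainr_fit_failure")
})

test_that("survival curve counts exceedance fractions", {
  sc <- survival_curve(c(1000, 2000, 4000))
  expect_equal(sc$survival[sc$distance_nt == 2000], 2 / 3)
  expect_equal(sc$survival[sc$distance_nt == 1000], 1)

  single <- survival_curve(5000)
  expect_equal(single$survival, 1)

  expect_error(survival_curve(numeric()), class = "curtainr_insufficient_data")
  expect_error(survival_curve(c(-5, 10)), class = "curtainr_invalid_parameter")
})

test_that("survival of many exponential draws matches the closed form", {
  set.seed(3)
  d <- rexp(1e4, 1 / 1e4) # mean 10 000 nt
  sc <- survival_curve(d)
  at <- which.min(abs(sc$distance_nt - 6931))
  expect_equal(sc$survival[at], 0.5, tolerance = 0.02 / 0.5)
})

test_that("processivity fit recovers the half-life of exponential draws", {
  set.seed(4)
  d <- rexp(1e4, 1 / 1e4)
  fit <- fit_processivity(d, n_boot = 50, seed = 11)
  expect_equal(fit$half_life, log(2) * 1e4, tolerance = 0.02)
  # half-life identity
  expect_equal(fit$half_life * fit$lambda, log(2), tolerance = 1e-9)
  # bootstrap CI contains the point estimate
  expect_true(fit$ci[1] <= fit$half_life && fit$half_life <= fit$ci[2])
})

test_that("processivity fit errors on degenerate input", {
  expect_error(fit_processivity(rep(5000, 20)), class = "curtainr_fit_failure")
  expect_error(fit_processivity(rexp(5, 1e-4)), class = "curtainr_insufficient_data")
})

test_that("detection-threshold offset removes left-truncation bias", {
  set.seed(5)
  hl <- 9500
  d <- rexp(3e4, log(2) / hl)
  d <- d[d >= 1450][1:2000]
  plain <- fit_processivity(d, n_boot = 10, seed = 1)$half_life
  corrected <- fit_processivity(d, n_boot = 10, seed = 1, d_min = 1450)$half_life
  expect_equal(corrected, hl, tolerance = 0.05)
  expect_gt(plain, corrected) # uncorrected fit overestimates
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  set.seed(6)
  widths <- vapply(c(50, 200, 800), function(n) {
    d <- rexp(n, 1e-4)
    f <- fit_processivity(d, n_boot = 200, seed = n)
    diff(f$ci)
  }, numeric(1))
  expect_true(widths[1] > widths[2] && widths[2] > widths[3])
  ratio <- widths[1] / widths[3] # expect ~ sqrt(800/50) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})

test_that("exchange-rate fit is exact on noise-free curves", {
  tr <- simulate_exchange_curve("decay", A = 1, k = 0.01, duration = 600, dt = 5)
  fit <- fit_exchange_rate(tr, "decay")
  expect_equal(fit$k, 0.01, tolerance = 1e-6)
  expect_equal(fit$A, 1, tolerance = 1e-6)

  rec <- simulate_exchange_curve("recovery", A = 2, k = 0.005, duration = 1200, dt = 5)
  fit2 <- fit_exchange_rate(rec, "recovery")
  expect_equal(fit2$k, 0.005, tolerance = 1e-6)
  expect_equal(fit2$A, 2, tolerance = 1e-6)
})

test_that("flat traces give a flagged near-zero rate", {
  flat <- tibble::tibble(time_s = seq(0, 100, 5), intensity = 1)
  expect_warning(fit <- fit_exchange_rate(flat, "decay"),
                 class = "curtainr_near_zero_rate")
  expect_equal(fit$k, 0)
  expect_true(fit$near_zero_rate)
})

test_that("noisy recovery curves yield the dissociation rate within 10%", {
  k_true <- dmc1_kinetics_preset()$k_off
  ks <- vapply(1:20, function(i) {
    tr <- simulate_exchange_curve("recovery", A = 1, k = k_true, noise_sd = 0.05,
                                  duration = 1500, dt = 10, seed = 400 + i)
    fit_exchange_rate(tr, "recovery")$k
  }, numeric(1))
  expect_equal(mean(ks), k_true, tolerance = 0.1)
})

test_that("monomer accounting divides by the filament footprint", {
  expect_equal(monomers_per_second(59), 59 / 3)
  expect_equal(round(monomers_per_second(59)), 20)
  expect_equal(monomers_per_second(0), 0)
  expect_equal(monomers_per_event(10300), 10300 / 3)
  expect_equal(round(monomers_per_event(10300)), 3433)
  expect_error(monomers_per_second(59, footprint = 0),
               class = "curtainr_invalid_parameter")
})
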