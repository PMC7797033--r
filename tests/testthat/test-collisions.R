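coll_imaging <- function(noise = FALSE) {
  im <- imaging_model(n_pixels = 70)
  if (noise) im else noise_free(im)
}

coll_motor <- function() motor_model(60, 10, 8000)

test_that("locate_joint finds a stationary punctum to sub-pixel accuracy", {
  cm <- collision_model(1, heteroduplex_position = 20000)
  mv <- simulate_collision_movie(cm, coll_motor(), coll_imaging(), seed = 1,
                                 pathway = "direct", outcome = "stall")
  j <- locate_joint(mv$kymographs$joint)
  expect_lt(abs(j$position_nt - 20000), 362.5) # half a pixel

  # noisy movie: within one pixel
  mv2 <- simulate_collision_movie(cm, coll_motor(), coll_imaging(noise = TRUE),
                                  seed = 2, pathway = "direct", outcome = "stall")
  j2 <- locate_joint(mv2$kymographs$joint)
  expect_lt(abs(j2$position_nt - 20000), 725)
})

test_that("absent or duplicated joints raise the specific errors", {
  im <- coll_imaging()
  dark <- as_kymograph(matrix(0, 30, 70), im, "joint")
  expect_error(locate_joint(dark), class = "curtainr_no_joint")

  two <- matrix(0, 30, 70)
  ctr <- (0:69) + 0.5
  for (f in 1:30) {
    two[f, ] <- 100 * exp(-(ctr - 20)^2 / 2) + 100 * exp(-(ctr - 45)^2 / 2)
  }
  expect_error(locate_joint(as_kymograph(two, im, "joint")),
               class = "curtainr_ambiguous_joint")
})

test_that("each simulated encounter category classifies as itself", {
  cm <- collision_model(0.5, heteroduplex_position = 20000,
                        direct_outcomes = c(stall = 1, disrupt = 0, other = 0))
  cases <- list(
    c("direct", "stall"), c("direct", "disrupt"), c("direct", "other"),
    c("translocation", "stall"), c("translocation", "bypass"),
    c("translocation", "other")
  )
  for (i in seq_along(cases)) {
    mv <- simulate_collision_movie(cm, coll_motor(), coll_imaging(), seed = 10 + i,
                                   pathway = cases[[i]][1], outcome = cases[[i]][2])
    cls <- classify_collision_movie(mv)
    expect_equal(cls$pathway, cases[[i]][1], label = paste(cases[[i]], collapse = "-"))
    expect_equal(cls$outcome, cases[[i]][2], label = paste(cases[[i]], collapse = "-"))
  }
})

test_that("classification is invariant to uniform intensity rescaling", {
  cm <- collision_model(1, heteroduplex_position = 20000)
  mv <- simulate_collision_movie(cm, coll_motor(), coll_imaging(), seed = 31,
                                 pathway = "translocation", outcome = "bypass")
  scaled <- mv$kymographs
  scaled$motor$data <- scaled$motor$data * 7.3
  scaled$joint$data <- scaled$joint$data * 0.2
  expect_equal(classify_collision_movie(mv)$outcome,
               classify_collision_movie(scaled)$outcome)
})

test_that("noise-free cohort classification is near-perfect", {
  pre <- collision_preset()
  scaled <- pre$counts
  scaled$n <- c(10L, 4L, 2L, 8L, 4L, 1L) # small replica of the category table
  cohort <- simulate_collision_cohort(pre$model, coll_motor(), coll_imaging(),
                                      counts = scaled, seed = 8)
  cls <- purrr::map_dfr(cohort$movies, classify_collision_movie)
  agree <- cls$pathway == cohort$truth$pathway & cls$outcome == cohort$truth$outcome
  expect_gte(mean(agree), 0.98)
})

test_that("tallies report nested fractions with counts", {
  ev <- tibble::tibble(
    pathway = rep(c("direct", "translocation"), c(95, 57)),
    outcome = c(rep("stall", 77), rep("disrupt", 16), rep("other", 2),
                rep("stall", 46), rep("bypass", 10), rep("other", 1))
  )
  tall <- tally_outcomes(ev)
  direct <- tall[tall$level == "pathway" & tall$pathway == "direct", ]
  expect_equal(direct$n, 95)
  expect_equal(direct$percent, 100 * 95 / 152, tolerance = 1e-12)
  ds <- tall[tall$level == "outcome" & tall$pathway == "direct" &
               tall$outcome == "stall", ]
  expect_equal(ds$percent, 100 * 77 / 95, tolerance = 1e-12)
  # fractions at each level sum to 100%
  expect_equal(sum(tall$percent[tall$level == "pathway"]), 100)
  for (p in c("direct", "translocation")) {
    expect_equal(sum(tall$percent[tall$level == "outcome" & tall$pathway == p]), 100)
  }

  one <- tally_outcomes(tibble::tibble(pathway = "direct", outcome = "stall"))
  expect_equal(one$percent[one$level == "pathway"], 100)
  expect_error(tally_outcomes(ev[0, ]), class = "curtainr_insufficient_data")
})

test_that("end-trace scoring reproduces a fixed positive/negative tally", {
  traces <- simulate_end_traces(12, 3, seed = 4)
  scored <- score_end_foci(traces)
  expect_equal(scored$focus_detected, attr(traces, "truth"))
  s <- attr(scored, "summary")
  expect_equal(s$percent, 100 * 12 / 15, tolerance = 1e-12)
})
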