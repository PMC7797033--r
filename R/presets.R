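#' Figure-panel presets for curtain simulations
#'
#' Each preset encodes a published condition's fitted translocation velocity
#' (Gaussian mean +/- sd, nt/s), processivity (survival half-life, nt) and
#' event count as simulator ground truth, so that the full
#' simulate -> render -> track -> fit pipeline can be checked for parameter
#' recovery at realistic sample sizes.
#'
#' Presets:
#' \describe{
#'   \item{fig2HI}{GFP-tagged motor on RPA-coated ssDNA: 68 +/- 19 nt/s,
#'     7900 nt, N = 54; labeled motor tracked as a punctum.}
#'   \item{fig4DE}{Unlabeled motor stripping RAD51, RPA-GFP exchange trail:
#'     59 +/- 17 nt/s, 9500 nt, N = 152; exchange-front tracking.}
#'   \item{fig4FG}{GFP-tagged motor on RAD51 filaments: 58 +/- 32 nt/s,
#'     10300 nt, N = 174.}
#'   \item{fig5DE}{RAD51-interaction-deficient mutant motor: 28 +/- 12 nt/s,
#'     5200 nt, N = 77.}
#'   \item{fig6BC}{Unlabeled motor on ATPase-dead RAD51-K133R filaments:
#'     54 +/- 22 nt/s, 9500 nt, N = 67.}
#'   \item{fig6EF}{Unlabeled motor on tight-binding RAD51-I287T filaments:
#'     49 +/- 16 nt/s, 6100 nt, N = 44.}
#'   \item{fig7CE}{Unlabeled motor on DMC1 filaments: 53 +/- 28 nt/s,
#'     4600 nt, N = 41.}
#'   \item{fig7DF}{GFP-tagged motor on DMC1 filaments: 54 +/- 23 nt/s,
#'     6300 nt, N = 69.}
#' }
#'
#' Simulated molecules are 150 knt (rolling-circle ssDNA substrates exceed
#' the ~50 knt minimum by a wide margin), observed for 1200 s with binding
#' confined to a 300 s injection window, so that runs are rarely censored by
#' the 5' end or the movie end and the survival fit is a meaningful estimate
#' of the run-length half-life.
#'
#' @param name Preset name (see above).
#' @return A list with elements `motor` ([motor_model()]), `imaging`
#'   ([imaging_model()]), `n_events`, `ssDNA_length`, `duration`,
#'   `bind_window`, `track` (`"front"` or `"puncta"`) and `truth`
#'   (the encoded velocity/processivity ground truth).
#' @export
curtain_preset <- function(name) {
  presets <- list(
    fig2HI = list(v = 68, sd = 19, hl = 7900, n = 54, mode = "exchange", labeled = TRUE),
    fig4DE = list(v = 59, sd = 17, hl = 9500, n = 152, mode = "exchange", labeled = FALSE),
    fig4FG = list(v = 58, sd = 32, hl = 10300, n = 174, mode = "exchange", labeled = TRUE),
    fig5DE = list(v = 28, sd = 12, hl = 5200, n = 77, mode = "exchange", labeled = FALSE),
    fig6BC = list(v = 54, sd = 22, hl = 9500, n = 67, mode = "exchange", labeled = FALSE),
    fig6EF = list(v = 49, sd = 16, hl = 6100, n = 44, mode = "exchange", labeled = FALSE),
    fig7CE = list(v = 53, sd = 28, hl = 4600, n = 41, mode = "exchange", labeled = FALSE),
    fig7DF = list(v = 54, sd = 23, hl = 6300, n = 69, mode = "exchange", labeled = TRUE)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets)) {
    abort(sprintf(
      "Unknown preset '%s'. Available: %s.",
      if (is.character(name)) name[1] else "<non-string>",
      paste(names(presets), collapse = ", ")
    ), class = "curtainr_config_error")
  }
  p <- presets[[name]]
  ssDNA_length <- 150000
  imaging <- imaging_model(n_pixels = ceiling(ssDNA_length / 725) + 1L)
  list(
    name = name,
    motor = motor_model(p$v, p$sd, p$hl, mode = p$mode, motor_labeled = p$labeled),
    imaging = imaging,
    n_events = p$n,
    ssDNA_length = ssDNA_length,
    duration = 1200,
    bind_window = 300,
    track = if (p$labeled) "puncta" else "front",
    truth = list(velocity_mean = p$v, velocity_sd = p$sd,
                 processivity_halflife = p$hl, n = p$n)
  )
}

#' Heteroduplex collision preset
#'
#' Event-category counts for the heteroduplex-encounter fixture cohort:
#' 95/152 direct recruitment (77 stall, 16 disrupt, 2 other) and 57/152
#' translocation collisions (46 stall, 10 bypass, 1 other). Subcategory
#' counts that do not sum to the pathway totals are carried as an explicit
#' "other" category.
#'
#' @return A list with `model` ([collision_model()]) and `counts` (a tibble
#'   of pathway/outcome counts, n = 152).
#' @export
collision_preset <- function() {
  counts <- tibble(
    pathway = c("direct", "direct", "direct", "translocation", "translocation", "translocation"),
    outcome = c("stall", "disrupt", "other", "stall", "bypass", "other"),
    n = c(77L, 16L, 2L, 46L, 10L, 1L)
  )
  model <- collision_model(
    p_direct = 95 / 152,
    direct_outcomes = c(stall = 77 / 95, disrupt = 16 / 95, other = 2 / 95),
    transloc_outcomes = c(stall = 46 / 57, bypass = 10 / 57, other = 1 / 57),
    heteroduplex_position = 20000
  )
  list(model = model, counts = counts)
}

#' DMC1 filament kinetics preset
#'
#' Ground-truth assembly and dissociation rate constants for simulated DMC1
#' exchange curves: spontaneous assembly k_on = 1.7e-3 1/s (decay of the
#' RPA-GFP coat signal) and dissociation k_off = 2.7e-3 1/s (recovery of
#' RPA-GFP rebinding).
#'
#' @return A list with `k_on` and `k_off`, 1/s.
#' @export
dmc1_kinetics_preset <- function() {
  list(k_on = 1.7e-3, k_off = 2.7e-3)
}

#' Photobleaching cohort fixture counts
#'
#' Ground-truth fluorophore counts for the 22-trace photobleaching fixture:
#' 3 single-GFP puncta and 19 multimeric puncta (2-4 GFPs), matching the
#' published tally of 3/22 single-step and 19/22 multi-step complexes.
#'
#' @return Integer vector of length 22 with the true fluorophore count per trace.
#' @export
photobleach_fixture_counts <- function() {
  c(rep(1L, 3L), rep(2L, 8L), rep(3L, 7L), rep(4L, 4L))
}

#' Generate the 22-trace photobleaching fixture
#'
#' Builds one noise-free (or noisy) trace per fixture count via
#' [simulate_photobleach_trace()]. Bleach times are redrawn until all
#' within-trace gaps exceed `min_separation`, so every bleaching event is
#' resolvable as its own step at the trace's sampling interval — the
#' fixture's purpose is an exact class tally, which unresolvable
#' same-sample double steps would corrupt.
#'
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise SD per sample.
#' @param min_separation Minimum gap between bleach times, s.
#' @param duration,dt Trace length and sampling interval, s.
#' @return List of `intensity_trace` objects with truth attributes.
#' @export
photobleach_fixture_traces <- function(seed = 1, noise_sd = 0,
                                       min_separation = 2, duration = 400,
                                       dt = 0.5) {
  counts <- photobleach_fixture_counts()
  traces <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    attempt <- 0L
    repeat {
      tr <- simulate_photobleach_trace(
        counts[i], noise_sd = noise_sd, duration = duration, dt = dt,
        seed = derive_seed(seed, i * 100L + attempt)
      )
      bt <- attr(tr, "bleach_times")
      ok <- all(bt <= duration - 5) &&
        (length(bt) < 2L || min(diff(sort(bt))) >= min_separation)
      if (ok || attempt > 200L) break
      attempt <- attempt + 1L
    }
    traces[[i]] <- tr
  }
  structure(traces, counts = counts, seed = seed)
}
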