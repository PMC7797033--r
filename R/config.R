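#' Build and validate a run configuration
#'
#' A run configuration ties a command to a preset (or explicit parameters),
#' a seed and an output directory. It can be given as a list or as a path
#' to a YAML/JSON file. Every stochastic run records its seed and the fully
#' resolved configuration in the output manifest.
#'
#' @param x A list, or path to a `.yaml`/`.yml`/`.json` config file.
#' @return A validated `run_config` list with elements `experiment`
#'   (`"translocation"`, `"photobleach"`, `"bli"` or `"collisions"`),
#'   `preset`, `seed`, `out_dir`, `params` (overrides).
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(sprintf("Config file not found: %s", x), class = "curtainr_io_error")
    x <- if (grepl("\\.json$", x)) {
      jsonlite::read_json(x, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(x)
    }
  }
  if (!is.list(x)) abort("Config must be a list or a YAML/JSON file path.",
                         class = "curtainr_config_error")
  experiment <- x$experiment %||% "translocation"
  if (!experiment %in% c("translocation", "photobleach", "bli", "collisions")) {
    abort(sprintf("Unknown experiment '%s'.", experiment), class = "curtainr_config_error")
  }
  if (is.null(x$seed)) abort("Config must set a `seed`.", class = "curtainr_config_error")
  if (experiment == "translocation") {
    preset <- x$preset %||% "fig2HI"
    curtain_preset(preset) # validates the name
  } else {
    preset <- x$preset %||% NULL
  }
  structure(
    list(
      experiment = experiment, preset = preset,
      seed = as.integer(x$seed),
      out_dir = x$out_dir %||% ".",
      params = x$params %||% list()
    ),
    class = "run_config"
  )
}

write_manifest <- function(out_dir, config, files, extra = list()) {
  manifest <- c(
    list(
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = config$seed,
      config = unclass(config),
      files = lapply(files, function(f) {
        list(path = basename(f), md5 = unname(tools::md5sum(f)))
      })
    ),
    extra
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Simulate an experiment to disk
#'
#' Writes the simulated data files, the ground-truth log (JSON) and a
#' manifest (JSON, with per-file MD5 checksums and the resolved
#' configuration) into `config$out_dir`.
#'
#' @param config A [run_config()] (or list/path coercible to one).
#' @return The manifest as a list, invisibly; side effect: files on disk.
#' @export
cmd_simulate <- function(config) {
  config <- run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  files <- character()

  if (config$experiment == "translocation") {
    preset <- curtain_preset(config$preset)
    if (!is.null(p$n_events)) preset$n_events <- p$n_events
    imaging <- preset$imaging
    if (isFALSE(p$noise)) imaging <- noise_free(imaging)
    truth <- simulate_translocation_events(
      preset$motor, preset$ssDNA_length, preset$duration,
      seed = config$seed, n_events = preset$n_events,
      bind_window = preset$bind_window
    )
    for (i in seq_len(nrow(truth))) {
      one <- truth[i, ]
      attr(one, "motor") <- attr(truth, "motor")
      attr(one, "ssDNA_length") <- attr(truth, "ssDNA_length")
      attr(one, "duration") <- attr(truth, "duration")
      class(one) <- class(truth)
      kymos <- render_kymograph(one, imaging, seed = derive_seed(config$seed, i))
      for (ch in names(kymos)) {
        f <- file.path(out, sprintf("event%03d_%s.csv", i, ch))
        write_kymograph_csv(kymos[[ch]], f)
        files <- c(files, f)
      }
    }
    truth_file <- file.path(out, "truth.json")
    jsonlite::write_json(as_tibble(as.data.frame(truth)), truth_file,
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, truth_file)
    extra <- list(n_events = nrow(truth), preset = preset$name,
                  track = preset$track, mode = preset$motor$mode)
  } else if (config$experiment == "photobleach") {
    counts <- p$counts %||% photobleach_fixture_counts()
    noise_sd <- p$noise_sd %||% 0
    truths <- list()
    for (i in seq_along(counts)) {
      tr <- simulate_photobleach_trace(
        counts[i], noise_sd = noise_sd, seed = derive_seed(config$seed, i)
      )
      f <- file.path(out, sprintf("trace%03d.csv", i))
      write_trace_csv(tr, f)
      files <- c(files, f)
      truths[[i]] <- list(trace = i, n_fluorophores = counts[i],
                          bleach_times = attr(tr, "bleach_times"))
    }
    truth_file <- file.path(out, "truth.json")
    jsonlite::write_json(truths, truth_file, auto_unbox = TRUE, digits = NA)
    files <- c(files, truth_file)
    extra <- list(n_traces = length(counts))
  } else if (config$experiment == "bli") {
    diss_test <- p$dissociation %||% list(fast_amp = 0.4, fast_k = 0.05,
                                          slow_amp = 0.6, slow_k = 0.002)
    diss_ctrl <- p$control_dissociation %||%
      list(fast_amp = 0, fast_k = 0.05,
           slow_amp = diss_test$slow_amp + diss_test$fast_amp, slow_k = diss_test$slow_k)
    noise_sd <- p$noise_sd %||% 0
    test <- simulate_bli_sensorgram(dissociation = diss_test, noise_sd = noise_sd,
                                    seed = config$seed)
    ctrl <- simulate_bli_sensorgram(dissociation = diss_ctrl, noise_sd = noise_sd,
                                    seed = config$seed + 1L)
    f1 <- file.path(out, "sensorgram_test.csv")
    f2 <- file.path(out, "sensorgram_control.csv")
    write_trace_csv(test |> dplyr::rename(intensity = "signal_nm"), f1)
    write_trace_csv(ctrl |> dplyr::rename(intensity = "signal_nm"), f2)
    sched_file <- file.path(out, "schedule.json")
    jsonlite::write_json(attr(test, "schedule"), sched_file, auto_unbox = TRUE, digits = NA)
    files <- c(files, f1, f2, sched_file)
    extra <- list(dissociation = diss_test)
  } else { # collisions
    preset <- collision_preset()
    counts <- p$counts %||% preset$counts
    motor <- motor_model(60, 15, 8000)
    imaging <- imaging_model(photon_gain = if (isFALSE(p$noise)) 0 else 1,
                             read_noise = if (isFALSE(p$noise)) 0 else 1)
    cohort <- simulate_collision_cohort(preset$model, motor, imaging,
                                        counts = counts, seed = config$seed)
    for (i in seq_along(cohort$movies)) {
      for (ch in c("motor", "joint")) {
        f <- file.path(out, sprintf("movie%03d_%s.csv", i, ch))
        write_kymograph_csv(cohort$movies[[i]]$kymographs[[ch]], f)
        files <- c(files, f)
      }
    }
    truth_file <- file.path(out, "truth.json")
    jsonlite::write_json(cohort$truth, truth_file, auto_unbox = TRUE, digits = NA)
    files <- c(files, truth_file)
    extra <- list(n_movies = length(cohort$movies))
  }

  manifest_path <- write_manifest(out, config, files, extra)
  invisible(jsonlite::read_json(manifest_path))
}

#' Analyze a simulated (or imported) experiment directory
#'
#' Reads the input files of `config$out_dir`, runs the analysis route for
#' the configured experiment and writes `report.json` with the fitted
#' values, confidence intervals and counts.
#'
#' @param config A [run_config()] (or list/path coercible to one).
#' @return The report as a list (also written to `report.json`).
#' @export
cmd_analyze <- function(config) {
  config <- run_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) {
    abort(sprintf("Input directory not found: %s", out), class = "curtainr_io_error")
  }

  report <- if (config$experiment == "translocation") {
    preset <- curtain_preset(config$preset)
    kymo_files <- sort(list.files(out, pattern = "^event\\d+_", full.names = TRUE))
    if (length(kymo_files) == 0L) {
      abort(sprintf("No kymograph CSVs found in %s", out), class = "curtainr_io_error")
    }
    ids <- unique(sub("_(trail|coat|motor)\\.csv$", "", basename(kymo_files)))
    events <- purrr::map_dfr(ids, function(id) {
      chs <- list.files(out, pattern = paste0("^", id, "_"), full.names = TRUE)
      kymos <- list()
      for (f in chs) {
        ch <- sub("\\.csv$", "", sub(paste0("^", id, "_"), "", basename(f)))
        kymos[[ch]] <- read_kymograph_csv(f, preset$imaging, channel = ch)
      }
      track_translocation(kymos, track = preset$track, mode = preset$motor$mode)
    })
    if (nrow(events) < 10L) abort_insufficient("Fewer than 10 recovered events.")
    vfit <- fit_velocity_distribution(events$velocity_nt_s)
    sfit <- fit_processivity(events$distance_nt[!events$censored],
                             seed = config$seed + 1L, d_min = 1450)
    ev_file <- file.path(out, "events.csv")
    write_events_csv(events, ev_file)
    list(
      experiment = "translocation", preset = preset$name,
      velocity_mu = vfit$mu, velocity_sigma = vfit$sigma,
      half_life = sfit$half_life, half_life_ci = sfit$ci,
      n = vfit$n, n_uncensored = sfit$n,
      monomers_per_s = monomers_per_second(vfit$mu), seed = config$seed
    )
  } else if (config$experiment == "photobleach") {
    trace_files <- sort(list.files(out, pattern = "^trace\\d+\\.csv$", full.names = TRUE))
    if (length(trace_files) == 0L) {
      abort(sprintf("No trace CSVs found in %s", out), class = "curtainr_io_error")
    }
    calls <- purrr::map(trace_files, ~ count_steps(read_trace_csv(.x)))
    cohort <- classify_cohort(calls)
    readr::write_csv(cohort, file.path(out, "cohort.csv"))
    multi <- cohort |> filter(.data$classification == "multi")
    list(
      experiment = "photobleach", n = unique(cohort$total),
      n_multi = multi$n, percent_multi = multi$percent,
      per_trace = vapply(calls, function(x) x$n_steps, numeric(1)),
      seed = config$seed
    )
  } else if (config$experiment == "bli") {
    sched <- as_tibble(jsonlite::read_json(file.path(out, "schedule.json"),
                                           simplifyVector = TRUE))
    test <- read_sensorgram_csv(file.path(out, "sensorgram_test.csv"), sched)
    ctrl <- read_sensorgram_csv(file.path(out, "sensorgram_control.csv"), sched)
    diff <- normalize_and_subtract(test, ctrl)
    fit <- fit_biphasic(test |> filter(.data$phase == "dissociation"))
    readr::write_csv(diff, file.path(out, "dissociation_difference.csv"))
    list(
      experiment = "bli",
      fast_amp = fit$fast_amp, fast_k = fit$fast_k,
      slow_amp = fit$slow_amp, slow_k = fit$slow_k,
      single_fallback = fit$single, seed = config$seed
    )
  } else { # collisions
    motor_files <- sort(list.files(out, pattern = "^movie\\d+_motor\\.csv$", full.names = TRUE))
    if (length(motor_files) == 0L) {
      abort(sprintf("No movie CSVs found in %s", out), class = "curtainr_io_error")
    }
    imaging <- imaging_model()
    events <- purrr::map_dfr(motor_files, function(f) {
      jf <- sub("_motor\\.csv$", "_joint.csv", f)
      kymos <- list(
        motor = read_kymograph_csv(f, imaging, "motor"),
        joint = read_kymograph_csv(jf, imaging, "joint")
      )
      classify_collision_movie(kymos)
    })
    tall <- tally_outcomes(events)
    readr::write_csv(tall, file.path(out, "tally.csv"))
    direct <- tall |> filter(.data$level == "pathway", .data$pathway == "direct")
    ds <- tall |> filter(.data$level == "outcome", .data$pathway == "direct",
                         .data$outcome == "stall")
    list(
      experiment = "collisions", n = nrow(events),
      percent_direct = direct$percent, percent_direct_stall = ds$percent,
      seed = config$seed
    )
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' Combine analysis reports into a comparison table
#'
#' @param reports Character paths to `report.json` files, or a list of
#'   report lists.
#' @param out Optional CSV path for the combined table.
#' @return A tibble, one row per condition, with the headline quantities.
#' @export
cmd_report <- function(reports, out = NULL) {
  if (length(reports) == 0L) abort_insufficient("No reports supplied.")
  reps <- purrr::map(reports, function(r) {
    if (is.character(r)) jsonlite::read_json(r, simplifyVector = TRUE) else r
  })
  rows <- purrr::map_dfr(reps, function(r) {
    if (is.null(r$experiment)) {
      abort("Report lacks an `experiment` field.", class = "curtainr_validation_error")
    }
    if (identical(r$experiment, "translocation")) {
      for (fld in c("velocity_mu", "half_life", "n")) {
        if (is.null(r[[fld]])) {
          abort(sprintf("Translocation report lacks `%s`.", fld),
                class = "curtainr_validation_error")
        }
      }
      tibble(
        experiment = r$experiment, condition = r$preset %||% NA_character_,
        velocity_mu = r$velocity_mu, velocity_sigma = r$velocity_sigma,
        half_life = r$half_life,
        half_life_lo = r$half_life_ci[[1]], half_life_hi = r$half_life_ci[[2]],
        n = r$n, monomers_per_s = r$monomers_per_s
      )
    } else {
      tibble(
        experiment = r$experiment, condition = r$preset %||% NA_character_,
        velocity_mu = NA_real_, velocity_sigma = NA_real_,
        half_life = NA_real_, half_life_lo = NA_real_, half_life_hi = NA_real_,
        n = r$n %||% NA_integer_, monomers_per_s = NA_real_
      )
    }
  })
  if (!is.null(out)) readr::write_csv(rows, out)
  rows
}
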