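#' Read and write kymographs, traces and event tables
#'
#' Kymographs are stored as headerless CSV matrices (rows = frames,
#' columns = pixels) or single-page TIFF; traces and sensorgrams as
#' two-column CSV with a `time,signal` header; event tables as CSV with
#' the standard column set.
#'
#' @param kymo A [as_kymograph()] object.
#' @param path File path.
#' @param imaging An [imaging_model()] describing the stored matrix.
#' @param channel Channel label to attach on read.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name curtain-io
NULL

#' @rdname curtain-io
#' @export
write_kymograph_csv <- function(kymo, path) {
  utils::write.table(kymo$data, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname curtain-io
#' @export
read_kymograph_csv <- function(path, imaging, channel = "ch1") {
  mat <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(mat) <- NULL
  as_kymograph(mat, imaging, channel = channel)
}

#' @rdname curtain-io
#' @export
write_kymograph_tiff <- function(kymo, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The 'tiff' package is required for TIFF output.")
  }
  m <- kymo$data
  tiff::writeTIFF(m / max(m, 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname curtain-io
#' @export
read_kymograph_tiff <- function(path, imaging, channel = "ch1") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The 'tiff' package is required for TIFF input.")
  }
  mat <- tiff::readTIFF(path)
  as_kymograph(mat, imaging, channel = channel)
}

#' @rdname curtain-io
#' @param trace A tibble with `time_s` and `intensity` (or `signal_nm`).
#' @export
write_trace_csv <- function(trace, path) {
  tr <- as_tibble(trace)
  ycol <- intersect(c("intensity", "signal_nm"), names(tr))[1]
  readr::write_csv(tibble(time = tr$time_s, signal = tr[[ycol]]), path)
  invisible(path)
}

#' @rdname curtain-io
#' @export
read_trace_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  new_intensity_trace(df$time, df$signal)
}

#' @rdname curtain-io
#' @export
read_sensorgram_csv <- function(path, schedule) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  segment_phases(tibble(time_s = df$time, signal_nm = df$signal), schedule)
}

#' @rdname curtain-io
#' @param events An event tibble from [segment_translocation()].
#' @export
write_events_csv <- function(events, path) {
  ev <- as_tibble(events)
  if (!"event_id" %in% names(ev)) ev$event_id <- seq_len(nrow(ev))
  if (!"channel" %in% names(ev)) ev$channel <- NA_character_
  readr::write_csv(
    ev |> select("event_id", "channel", "start_s", "end_s",
                 "velocity_nt_s", "distance_nt", "censored"),
    path
  )
  invisible(path)
}

#' @rdname curtain-io
#' @export
read_events_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
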