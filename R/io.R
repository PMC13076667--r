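# CSV readers/writers for the package's tabular interchange formats. All are
# thin wrappers over readr with column checks, so files round-trip through
# the corresponding analysis functions.

#' Read and write two-channel photometry recordings
#'
#' CSV layout: columns `time_s`, `f470`, `f405`.
#'
#' @param path File path.
#' @param rec Recording tibble (`time_s`, `f470`, `f405`).
#' @return `read_photometry_csv()` returns the recording tibble;
#'   `write_photometry_csv()` returns `path` invisibly.
#' @export
read_photometry_csv <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(rec, c("time_s", "f470", "f405"), "recording file")
  rec
}

#' @rdname read_photometry_csv
#' @export
write_photometry_csv <- function(rec, path) {
  check_columns(rec, c("time_s", "f470", "f405"), "rec")
  readr::write_csv(rec, path)
  invisible(path)
}

#' Read and write event lists
#'
#' CSV layout: columns `onset_s` and optionally `stimulus_label`.
#'
#' @param path File path.
#' @param events Events tibble.
#' @return `read_events_csv()` returns the events tibble.
#' @export
read_events_csv <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(ev, "onset_s", "events file")
  ev
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  check_columns(events, "onset_s", "events")
  readr::write_csv(events, path)
  invisible(path)
}

#' Read and write wide trace matrices
#'
#' CSV layout: column `time_s` plus one numeric column per neuron.
#'
#' @param path File path.
#' @param traces Wide traces tibble.
#' @return `read_traces_csv()` returns the traces tibble.
#' @export
read_traces_csv <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(tr, "time_s", "traces file")
  tr
}

#' @rdname read_traces_csv
#' @export
write_traces_csv <- function(traces, path) {
  check_columns(traces, "time_s", "traces")
  readr::write_csv(traces, path)
  invisible(path)
}

#' Read and write centroid tables
#'
#' CSV layout: columns `neuron_id`, `x_px`, `y_px`.
#'
#' @param path File path.
#' @param centroids Centroid tibble.
#' @return `read_centroids_csv()` returns the centroid tibble.
#' @export
read_centroids_csv <- function(path) {
  ce <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(ce, c("neuron_id", "x_px", "y_px"), "centroid file")
  ce
}

#' @rdname read_centroids_csv
#' @export
write_centroids_csv <- function(centroids, path) {
  check_columns(centroids, c("neuron_id", "x_px", "y_px"), "centroids")
  readr::write_csv(centroids, path)
  invisible(path)
}

#' Read and write region count tables
#'
#' CSV layout: columns `brain_id`, `region`, `raw_count`, `counting_mode`.
#'
#' @param path File path.
#' @param counts Region count tibble.
#' @return `read_region_counts_csv()` returns the count tibble.
#' @export
read_region_counts_csv <- function(path) {
  rc <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(rc, c("brain_id", "region", "raw_count", "counting_mode"),
                "region count file")
  rc
}

#' @rdname read_region_counts_csv
#' @export
write_region_counts_csv <- function(counts, path) {
  check_columns(counts, c("brain_id", "region", "raw_count", "counting_mode"),
                "counts")
  readr::write_csv(counts, path)
  invisible(path)
}
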