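#' Effective per-region input counts under mixed counting modes
#'
#' Retrograde-label counts are collected either from every third section
#' (the default protocol) or, for sparse regions, from every section (the
#' low-count rescue). To make both commensurate, every-section counts are
#' multiplied by `sampling_fraction` (default 1/3), putting all regions on
#' the every-third-section scale; every-third counts are kept as-is.
#' Effective counts may be fractional.
#'
#' @param counts Data frame with columns `brain_id`, `region`, `raw_count`,
#'   `counting_mode` (`"every_third"` or `"every_section"`), as produced by
#'   [sim_region_counts()] or [read_region_counts_csv()].
#' @param sampling_fraction Fraction of sections sampled by the default
#'   protocol, in (0, 1\].
#' @return The input tibble with an added `effective_count` column.
#' @examples
#' tbl <- tibble::tibble(brain_id = "b1", region = c("VS", "PFC"),
#'                       raw_count = c(30, 9),
#'                       counting_mode = c("every_third", "every_section"))
#' effective_counts(tbl)
#' @export
effective_counts <- function(counts, sampling_fraction = 1 / 3) {
  check_columns(counts, c("brain_id", "region", "raw_count", "counting_mode"),
                "counts")
  if (!is.numeric(sampling_fraction) || length(sampling_fraction) != 1L ||
      sampling_fraction <= 0 || sampling_fraction > 1) {
    abort("`sampling_fraction` must be in (0, 1].",
          class = "caensembles_parameter_error")
  }
  bad <- setdiff(unique(counts$counting_mode),
                 c("every_third", "every_section"))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown counting_mode: %s.",
                  paste0('"', bad, '"', collapse = ", ")),
          class = "caensembles_parameter_error")
  }
  if (any(counts$raw_count < 0) ||
      any(counts$raw_count != round(counts$raw_count))) {
    abort("`raw_count` must be non-negative integers.",
          class = "caensembles_parameter_error")
  }
  if (anyDuplicated(counts[c("brain_id", "region")])) {
    abort("Regions must be unique within each brain.",
          class = "caensembles_parameter_error")
  }
  dplyr::mutate(
    as_tibble(counts),
    effective_count = ifelse(.data$counting_mode == "every_section",
                             .data$raw_count * sampling_fraction,
                             .data$raw_count)
  )
}

#' Normalized monosynaptic input index
#'
#' Converts per-region labeled-input counts into per-brain input indices:
#' each region's effective count divided by the brain's total effective
#' count, so indices within a brain sum to 1 over the counted regions.
#' Per-brain normalization precedes any group averaging because total input
#' numbers vary between brains. No double-counting correction is applied.
#'
#' @inheritParams effective_counts
#' @return Tibble with columns `brain_id`, `region`, `raw_count`,
#'   `counting_mode`, `effective_count`, `input_index`.
#' @examples
#' sim <- sim_region_counts(n_brains = 2, seed = 1)
#' idx <- normalize_inputs(sim$counts)
#' dplyr::summarise(dplyr::group_by(idx, brain_id), total = sum(input_index))
#' @export
normalize_inputs <- function(counts, sampling_fraction = 1 / 3) {
  eff <- effective_counts(counts, sampling_fraction = sampling_fraction)
  totals <- eff |>
    dplyr::group_by(.data$brain_id) |>
    dplyr::summarise(total = sum(.data$effective_count), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort("Total effective count must be positive for every brain.",
          class = "caensembles_parameter_error")
  }
  eff |>
    dplyr::left_join(totals, by = "brain_id") |>
    dplyr::mutate(input_index = .data$effective_count / .data$total) |>
    dplyr::select(-"total")
}

#' Group summary of input indices across brains
#'
#' Averages per-brain input indices by region (optionally within groups,
#' e.g. the two labeled ensembles), with SEM across brains.
#'
#' @param index Output of [normalize_inputs()], optionally with a `group`
#'   column.
#' @return Tibble with columns (`group`,) `region`, `mean_index`,
#'   `sem_index`, `n_brains`.
#' @examples
#' sim <- sim_region_counts(n_brains = 4, seed = 1)
#' summarize_input_index(normalize_inputs(sim$counts))
#' @export
summarize_input_index <- function(index) {
  check_columns(index, c("brain_id", "region", "input_index"), "index")
  grouping <- if ("group" %in% names(index)) c("group", "region") else "region"
  index |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      mean_index = mean(.data$input_index),
      sem_index = sd(.data$input_index) / sqrt(dplyr::n()),
      n_brains = dplyr::n(),
      .groups = "drop"
    )
}
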