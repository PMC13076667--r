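#' Simulate per-brain rabies-tracing region count tables
#'
#' Emulates manual counting of retrogradely labeled input neurons from serial
#' coronal sections. For each brain and region, cells are distributed over
#' `n_sections` sections as independent Poisson counts; the counting protocol
#' samples every third section (random starting phase). Regions whose
#' every-third count falls below `low_count_threshold` are "recounted" from
#' every section and flagged `counting_mode = "every_section"`, mirroring the
#' low-count rescue convention; all other regions report the every-third
#' count with `counting_mode = "every_third"`.
#'
#' Per-brain total input numbers vary via a log-normal brain effect, which is
#' why downstream indices are normalized within brain before averaging
#' across brains.
#'
#' @param region_rates Named numeric vector: expected total labeled cells per
#'   region (over all sections) for an average brain. The default is a small
#'   set of canonical VTA input regions (ventral striatum, dorsomedial
#'   striatum, ventral pallidum, dorsal raphe, central amygdala, lateral
#'   hypothalamus, lateral habenula, prefrontal cortex).
#' @param n_brains Number of brains.
#' @param n_sections Number of sections spanning the counted volume.
#' @param low_count_threshold Raw every-third count below which the region is
#'   recounted from every section (default 5).
#' @param brain_effect_sd SD of the log-normal per-brain scaling of totals.
#' @param seed Integer seed.
#'
#' @return A list of class `"tracing_sim"`:
#'   * `counts`: tibble `brain_id`, `region`, `raw_count`, `counting_mode`;
#'   * `truth`: list with `section_totals` (tibble `brain_id`, `region`,
#'     `total_cells` = true total over all sections) and `expected_rates`.
#'
#' @examples
#' sim <- sim_region_counts(n_brains = 2, seed = 1)
#' sim$counts
#' @export
sim_region_counts <- function(region_rates = c(
                                VS = 300, DMS = 150, VP = 120, DRN = 100,
                                CeA = 80, LH = 60, LHb = 30, PFC = 9
                              ),
                              n_brains = 4,
                              n_sections = 90,
                              low_count_threshold = 5,
                              brain_effect_sd = 0.2,
                              seed = 1) {
  if (!is.numeric(region_rates) || is.null(names(region_rates)) ||
      any(!nzchar(names(region_rates))) || any(region_rates < 0)) {
    abort("`region_rates` must be a named non-negative numeric vector.",
          class = "caensembles_parameter_error")
  }
  if (anyDuplicated(names(region_rates))) {
    abort("`region_rates` names must be unique.",
          class = "caensembles_parameter_error")
  }
  check_positive_scalar(n_brains, "n_brains")
  check_positive_scalar(n_sections, "n_sections")
  check_nonneg_scalar(low_count_threshold, "low_count_threshold")
  check_nonneg_scalar(brain_effect_sd, "brain_effect_sd")
  n_brains <- as.integer(n_brains)
  n_sections <- as.integer(n_sections)

  with_sim_seed(seed, {
    rows <- list()
    truth_rows <- list()
    for (b in seq_len(n_brains)) {
      brain_id <- sprintf("brain%02d", b)
      effect <- exp(rnorm(1, 0, brain_effect_sd))
      for (r in names(region_rates)) {
        lambda_section <- region_rates[[r]] * effect / n_sections
        per_section <- stats::rpois(n_sections, lambda_section)
        total <- sum(per_section)
        phase <- sample.int(3, 1)                # random starting section
        third_idx <- seq(phase, n_sections, by = 3)
        third_count <- sum(per_section[third_idx])
        if (third_count < low_count_threshold) {
          rows[[length(rows) + 1L]] <- tibble(
            brain_id = brain_id, region = r,
            raw_count = total, counting_mode = "every_section"
          )
        } else {
          rows[[length(rows) + 1L]] <- tibble(
            brain_id = brain_id, region = r,
            raw_count = third_count, counting_mode = "every_third"
          )
        }
        truth_rows[[length(truth_rows) + 1L]] <- tibble(
          brain_id = brain_id, region = r, total_cells = total
        )
      }
    }
    structure(
      list(
        counts = dplyr::bind_rows(rows),
        truth = list(
          section_totals = dplyr::bind_rows(truth_rows),
          expected_rates = region_rates
        )
      ),
      class = "tracing_sim"
    )
  })
}

#' @export
print.tracing_sim <- function(x, ...) {
  cat(sprintf("<tracing_sim> %d brains x %d regions\n",
              length(unique(x$counts$brain_id)),
              length(unique(x$counts$region))))
  invisible(x)
}
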