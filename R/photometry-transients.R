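#' Detect significant calcium transients by MAD thresholding
#'
#' A transient epoch is a maximal run of samples in which dF/F stays at
#' least `sustain_mads` MADs above the baseline median, that contains at
#' least one sample exceeding `onset_mads` MADs above the baseline median,
#' and that lasts at least `min_duration_s`. The MAD is the raw median
#' absolute deviation of the baseline samples, *without* the 1.4826
#' normal-consistency factor, because the thresholds are quoted directly in
#' MAD units (2.91 raw MADs corresponds to ~1.96 sigma under Gaussian
#' noise, i.e. a two-sided 95% criterion).
#'
#' Baseline statistics are estimated in one of two modes:
#' * `"whole"` (default): median and MAD over the whole trace, followed by
#'   one re-estimation pass that excludes samples inside candidate epochs
#'   detected with the first-pass statistics (so large transients do not
#'   inflate their own baseline);
#' * `"pre_event"`: median and MAD over the samples strictly before the
#'   first event in `events` (requires `events`).
#'
#' A baseline MAD of zero means the trace has no resolvable noise floor and
#' thresholds are undefined; this raises an error of class
#' `"caensembles_degenerate_baseline_error"` rather than silently flooring
#' the variance.
#'
#' @param dff A `dff_tbl` from [compute_dff()], or any data frame with
#'   columns `time_s`, `dff`.
#' @param onset_mads Threshold a transient must exceed, in baseline MADs
#'   (default 2.91).
#' @param sustain_mads Level the epoch must remain above, in baseline MADs
#'   (default 2).
#' @param min_duration_s Minimum epoch duration in seconds (default 0.5).
#' @param baseline Baseline mode, `"whole"` or `"pre_event"`.
#' @param events Event onsets (numeric seconds, or a data frame with
#'   `onset_s`), required for `baseline = "pre_event"`.
#' @param min_baseline_samples Minimum number of baseline samples required.
#' @return Tibble with one row per epoch: `onset_s`, `offset_s`, `peak_dff`,
#'   `duration_s`; attributes `baseline_median` and `baseline_mad` record
#'   the statistics used.
#' @examples
#' sim <- sim_photometry(300, event_times = c(100, 200), transient_amp = 0.1,
#'                       artifact_amp = 0, noise_sd = 0.005, seed = 1)
#' dff <- compute_dff(sim$recording)
#' detect_transients(dff)
#' @export
detect_transients <- function(dff,
                              onset_mads = 2.91,
                              sustain_mads = 2,
                              min_duration_s = 0.5,
                              baseline = c("whole", "pre_event"),
                              events = NULL,
                              min_baseline_samples = 100) {
  check_columns(dff, c("time_s", "dff"), "dff")
  check_positive_scalar(onset_mads, "onset_mads")
  check_positive_scalar(sustain_mads, "sustain_mads")
  check_nonneg_scalar(min_duration_s, "min_duration_s")
  if (onset_mads < sustain_mads) {
    abort("`onset_mads` must be >= `sustain_mads`.",
          class = "caensembles_parameter_error")
  }
  baseline <- match.arg(baseline)
  fs <- attr(dff, "fs") %||% infer_fs(dff$time_s)
  x <- as.numeric(dff$dff)
  t <- as.numeric(dff$time_s)

  baseline_idx <- if (baseline == "pre_event") {
    if (is.null(events)) {
      abort("`events` is required for baseline = \"pre_event\".",
            class = "caensembles_parameter_error")
    }
    onsets <- if (is.data.frame(events)) events$onset_s else as.numeric(events)
    which(t < min(onsets))
  } else {
    seq_along(x)
  }
  baseline_idx <- baseline_idx[is.finite(x[baseline_idx])]
  if (length(baseline_idx) < min_baseline_samples) {
    abort(sprintf("Baseline segment has fewer than %d usable samples.",
                  min_baseline_samples),
          class = "caensembles_parameter_error")
  }

  raw_mad <- function(v) median(abs(v - median(v)))

  stats1 <- c(med = median(x[baseline_idx]), mad = raw_mad(x[baseline_idx]))
  if (stats1[["mad"]] == 0) {
    abort("Baseline MAD is zero; transient thresholds are undefined.",
          class = "caensembles_degenerate_baseline_error")
  }

  find_epochs <- function(med, mad_v) {
    above <- is.finite(x) & (x >= med + sustain_mads * mad_v)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    out <- list()
    for (k in runs) {
      i0 <- starts[k]
      i1 <- ends[k]
      dur <- (i1 - i0 + 1L) / fs
      if (dur < min_duration_s) next
      if (max(x[i0:i1]) < med + onset_mads * mad_v) next
      out[[length(out) + 1L]] <- c(i0 = i0, i1 = i1)
    }
    out
  }

  if (baseline == "whole") {
    # Re-estimate baseline statistics excluding first-pass candidate samples.
    cand <- find_epochs(stats1[["med"]], stats1[["mad"]])
    in_epoch <- rep(FALSE, length(x))
    for (e in cand) in_epoch[e[["i0"]]:e[["i1"]]] <- TRUE
    clean <- setdiff(baseline_idx, which(in_epoch))
    if (length(clean) >= min_baseline_samples) {
      stats1 <- c(med = median(x[clean]), mad = raw_mad(x[clean]))
      if (stats1[["mad"]] == 0) {
        abort("Baseline MAD is zero after epoch exclusion; thresholds undefined.",
              class = "caensembles_degenerate_baseline_error")
      }
    }
  }

  epochs <- find_epochs(stats1[["med"]], stats1[["mad"]])
  res <- if (length(epochs) == 0L) {
    tibble(onset_s = numeric(0), offset_s = numeric(0),
           peak_dff = numeric(0), duration_s = numeric(0))
  } else {
    dplyr::bind_rows(lapply(epochs, function(e) {
      i0 <- e[["i0"]]
      i1 <- e[["i1"]]
      tibble(onset_s = t[i0], offset_s = t[i1],
             peak_dff = max(x[i0:i1]),
             duration_s = (i1 - i0 + 1L) / fs)
    }))
  }
  structure(res,
            baseline_median = unname(stats1[["med"]]),
            baseline_mad = unname(stats1[["mad"]]))
}
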