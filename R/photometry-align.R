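#' Align dF/F to behavioral event onsets
#'
#' Extracts a peri-event segment of dF/F for each event onset, on a common
#' relative time grid from `-pre_s` to `+post_s` (native sampling grid).
#' Events whose full window does not fit inside the recording are dropped
#' and the dropped count is reported via a message; trial numbering follows
#' event order among the retained events.
#'
#' @param dff A `dff_tbl` from [compute_dff()], or a data frame with columns
#'   `time_s`, `dff`.
#' @param events Event onsets: a numeric vector of seconds, or a data frame
#'   with column `onset_s` (and optionally `stimulus_label`).
#' @param pre_s,post_s Window extent before/after each onset, seconds
#'   (defaults 10 and 10, the standard peri-event quantification window).
#' @return A tibble of class `"aligned_photometry"` in long format with
#'   columns `trial`, `rel_time_s`, `dff`; attributes `fs`, `pre_s`,
#'   `post_s`, `n_dropped`, `event_onsets`.
#' @examples
#' sim <- sim_photometry(200, event_times = c(60, 120), artifact_amp = 0,
#'                       seed = 1)
#' aligned <- align_photometry(compute_dff(sim$recording), c(60, 120))
#' dplyr::count(aligned, trial)
#' @export
align_photometry <- function(dff, events, pre_s = 10, post_s = 10) {
  check_columns(dff, c("time_s", "dff"), "dff")
  check_positive_scalar(pre_s, "pre_s")
  check_positive_scalar(post_s, "post_s")
  onsets <- if (is.data.frame(events)) {
    check_columns(events, "onset_s", "events")
    as.numeric(events$onset_s)
  } else {
    as.numeric(events)
  }
  if (length(onsets) == 0L) {
    abort("No events supplied.", class = "caensembles_empty_alignment_error")
  }
  fs <- attr(dff, "fs") %||% infer_fs(dff$time_s)
  t <- dff$time_s
  x <- dff$dff
  n <- length(t)
  n_pre <- as.integer(round(pre_s * fs))
  n_post <- as.integer(round(post_s * fs))
  rel <- (-n_pre:n_post) / fs

  rows <- list()
  trial <- 0L
  n_dropped <- 0L
  kept_onsets <- numeric(0)
  for (te in onsets) {
    ic <- as.integer(round((te - t[1]) * fs)) + 1L
    i0 <- ic - n_pre
    i1 <- ic + n_post
    if (i0 < 1L || i1 > n) {
      n_dropped <- n_dropped + 1L
      next
    }
    trial <- trial + 1L
    kept_onsets <- c(kept_onsets, te)
    rows[[trial]] <- tibble(trial = trial, rel_time_s = rel, dff = x[i0:i1])
  }
  if (n_dropped > 0L) {
    inform(sprintf("Dropped %d event(s) without full [-%g, +%g] s support.",
                   n_dropped, pre_s, post_s))
  }
  if (trial == 0L) {
    abort("No events with full window support inside the recording.",
          class = "caensembles_empty_alignment_error")
  }
  structure(dplyr::bind_rows(rows),
            class = c("aligned_photometry", class(tibble())),
            fs = fs, pre_s = pre_s, post_s = post_s,
            n_dropped = n_dropped, event_onsets = kept_onsets)
}

#' Per-trial AUC and peak quantification of aligned dF/F
#'
#' For each trial, integrates dF/F (trapezoidal rule on the native grid)
#' over the baseline window (from `-pre_s` up to, but not including, the
#' event onset sample) and the stimulus window (onset to `+post_s`), and
#' takes the peak dF/F within the stimulus window. AUC units are dF/F x s.
#'
#' @param aligned An `"aligned_photometry"` object from [align_photometry()].
#' @return Tibble with one row per trial: `trial`, `baseline_auc`,
#'   `stim_auc`, `peak_dff`.
#' @examples
#' sim <- sim_photometry(200, event_times = c(60, 120), artifact_amp = 0,
#'                       seed = 1)
#' aligned <- align_photometry(compute_dff(sim$recording), c(60, 120))
#' quantify_auc_peak(aligned)
#' @export
quantify_auc_peak <- function(aligned) {
  check_columns(aligned, c("trial", "rel_time_s", "dff"), "aligned")
  if (nrow(aligned) == 0L) {
    abort("`aligned` is empty.", class = "caensembles_empty_alignment_error")
  }
  aligned |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(
      baseline_auc = pracma::trapz(.data$rel_time_s[.data$rel_time_s < 0],
                                   .data$dff[.data$rel_time_s < 0]),
      stim_auc = pracma::trapz(.data$rel_time_s[.data$rel_time_s >= 0],
                               .data$dff[.data$rel_time_s >= 0]),
      peak_dff = max(.data$dff[.data$rel_time_s >= 0]),
      .groups = "drop"
    )
}
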