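#' Align single-neuron traces to events and z-score against a pre-event baseline
#'
#' For each neuron and each event, extracts the peri-event segment on
#' \[-`pre_s`, +`post_s`\] seconds and z-scores it against that trial's own
#' baseline window: `z = (x - mean_baseline) / sd_baseline`, with the sample
#' SD (n - 1 denominator) of the baseline samples. The default windows are
#' a \[-10, +20\] s peri-event extent with a \[-2, 0) s baseline. Baseline
#' samples are those with relative time in `[baseline[1], baseline[2])` —
#' the onset sample itself belongs to the response, not the baseline.
#'
#' Baseline statistics are per neuron *and* per trial, which makes the
#' z-score robust to slow drift between trials and invariant to per-neuron
#' affine rescaling of raw fluorescence. Trials whose baseline has zero
#' variance for a neuron carry no usable noise scale; they are marked
#' invalid (`valid = FALSE`, `z = NA`) and excluded from downstream means
#' rather than patched with a variance floor.
#'
#' Events without full window support are dropped (message); if no event
#' survives, an error of class `"caensembles_empty_alignment_error"` is
#' raised.
#'
#' @param traces Wide data frame: column `time_s` plus one numeric column
#'   per neuron (as produced by [sim_ensemble_session()] or
#'   [read_traces_csv()]).
#' @param events Event onsets: numeric seconds or a data frame with
#'   `onset_s` (and optionally `stimulus_label`, see `stimulus`).
#' @param pre_s,post_s Peri-event extent, seconds.
#' @param baseline Length-2 numeric, baseline window in relative seconds
#'   (must lie within `[-pre_s, 0]`).
#' @param stimulus Optional stimulus label; when `events` has a
#'   `stimulus_label` column, only matching events are used, and the label is
#'   attached to the result.
#' @return A tibble of class `"aligned_tensor"` in long format with columns
#'   `neuron_id`, `trial`, `rel_time_s`, `z`, `valid`; attributes `fs`,
#'   `pre_s`, `post_s`, `baseline`, `stimulus_label`, `n_dropped`.
#' @examples
#' sim <- sim_ensemble_session(n_neurons = 8, seed = 1)
#' tens <- align_and_zscore(sim$traces, sim$events, stimulus = "A")
#' head(tens)
#' @export
align_and_zscore <- function(traces, events, pre_s = 10, post_s = 20,
                             baseline = c(-2, 0), stimulus = NULL) {
  check_columns(traces, "time_s", "traces")
  check_positive_scalar(pre_s, "pre_s")
  check_positive_scalar(post_s, "post_s")
  if (length(baseline) != 2L || baseline[1] >= baseline[2] ||
      baseline[1] < -pre_s || baseline[2] > 0) {
    abort("`baseline` must be (lo, hi) with -pre_s <= lo < hi <= 0.",
          class = "caensembles_parameter_error")
  }
  if (is.data.frame(events)) {
    check_columns(events, "onset_s", "events")
    if (!is.null(stimulus) && "stimulus_label" %in% names(events)) {
      events <- dplyr::filter(events, .data$stimulus_label == stimulus)
    }
    onsets <- as.numeric(events$onset_s)
  } else {
    onsets <- as.numeric(events)
  }
  if (length(onsets) == 0L) {
    abort("No events supplied (after stimulus filtering).",
          class = "caensembles_empty_alignment_error")
  }

  neuron_ids <- setdiff(names(traces), "time_s")
  if (length(neuron_ids) == 0L) {
    abort("`traces` has no neuron columns.",
          class = "caensembles_parameter_error")
  }
  if (anyDuplicated(neuron_ids)) {
    abort("Duplicate neuron ids in `traces`.",
          class = "caensembles_parameter_error")
  }
  t <- traces$time_s
  fs <- infer_fs(t)
  n <- length(t)
  n_pre <- as.integer(round(pre_s * fs))
  n_post <- as.integer(round(post_s * fs))
  rel <- (-n_pre:n_post) / fs
  base_bins <- which(rel >= baseline[1] & rel < baseline[2])
  if (length(base_bins) < 2L) {
    abort("Baseline window contains fewer than 2 samples.",
          class = "caensembles_parameter_error")
  }

  act <- as.matrix(traces[neuron_ids])
  if (!all(is.finite(act))) {
    abort("Trace matrix contains non-finite values.",
          class = "caensembles_parameter_error")
  }

  rows <- list()
  trial <- 0L
  n_dropped <- 0L
  for (te in onsets) {
    ic <- as.integer(round((te - t[1]) * fs)) + 1L
    i0 <- ic - n_pre
    i1 <- ic + n_post
    if (i0 < 1L || i1 > n) {
      n_dropped <- n_dropped + 1L
      next
    }
    trial <- trial + 1L
    seg <- act[i0:i1, , drop = FALSE]
    base <- seg[base_bins, , drop = FALSE]
    mu <- colMeans(base)
    sdv <- apply(base, 2, sd)
    z <- sweep(sweep(seg, 2, mu, "-"), 2, sdv, "/")
    invalid <- sdv == 0
    z[, invalid] <- NA_real_
    rows[[trial]] <- tibble(
      neuron_id = rep(neuron_ids, each = length(rel)),
      trial = trial,
      rel_time_s = rep(rel, times = length(neuron_ids)),
      z = as.vector(z),
      valid = rep(!invalid, each = length(rel))
    )
  }
  if (n_dropped > 0L) {
    inform(sprintf("Dropped %d event(s) without full [-%g, +%g] s support.",
                   n_dropped, pre_s, post_s))
  }
  if (trial == 0L) {
    abort("No events with full window support inside the recording.",
          class = "caensembles_empty_alignment_error")
  }
  out <- dplyr::bind_rows(rows)
  if (all(!out$valid)) {
    abort("All trials are invalid (zero baseline variance) for all neurons.",
          class = "caensembles_empty_alignment_error")
  }
  structure(out,
            class = c("aligned_tensor", class(tibble())),
            fs = fs, pre_s = pre_s, post_s = post_s, baseline = baseline,
            stimulus_label = stimulus %||% NA_character_,
            n_dropped = n_dropped)
}

#' Summarize per-neuron peri-event response
#'
#' Computes each neuron's mean z-score in the post-event window: first the
#' time-mean within each valid trial over `window` (default \[0, 20\] s),
#' then the mean across the first `n_trials` valid trials in event order
#' (default 4). Neurons with no valid trial are excluded and reported via
#' the `n_excluded` attribute and a message.
#'
#' @param tensor An `"aligned_tensor"` from [align_and_zscore()].
#' @param window Length-2 numeric, scoring window in relative seconds
#'   (closed interval).
#' @param n_trials Number of leading valid trials to average (default 4).
#' @return Tibble with columns `neuron_id`, `mean_z`, `n_trials_used`.
#' @examples
#' sim <- sim_ensemble_session(n_neurons = 8, seed = 1)
#' tens <- align_and_zscore(sim$traces, sim$events, stimulus = "A")
#' summarize_response(tens)
#' @export
summarize_response <- function(tensor, window = c(0, 20), n_trials = 4) {
  check_columns(tensor, c("neuron_id", "trial", "rel_time_s", "z", "valid"),
                "tensor")
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be (lo, hi) with lo < hi.",
          class = "caensembles_parameter_error")
  }
  check_positive_scalar(n_trials, "n_trials")

  all_ids <- unique(tensor$neuron_id)
  res <- tensor |>
    dplyr::filter(.data$valid,
                  .data$rel_time_s >= window[1],
                  .data$rel_time_s <= window[2]) |>
    dplyr::group_by(.data$neuron_id, .data$trial) |>
    dplyr::summarise(trial_mean = mean(.data$z), .groups = "drop_last") |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::summarise(
      mean_z = mean(.data$trial_mean[seq_len(min(n_trials, dplyr::n()))]),
      n_trials_used = min(n_trials, dplyr::n()),
      .groups = "drop"
    )
  excluded <- setdiff(all_ids, res$neuron_id)
  if (length(excluded) > 0L) {
    inform(sprintf("Excluded %d neuron(s) with no valid trial.",
                   length(excluded)))
  }
  res <- res[match(intersect(all_ids, res$neuron_id), res$neuron_id), ]
  structure(res, excluded = excluded, n_excluded = length(excluded))
}

#' Classify stimulus-responsive neurons
#'
#' A neuron is responsive to a stimulus when its mean post-event z-score
#' strictly exceeds `threshold` (default 1.5): a neuron at exactly the
#' threshold is not responsive.
#'
#' @param summary A response summary from [summarize_response()] (columns
#'   `neuron_id`, `mean_z`).
#' @param threshold Responsiveness threshold in z units (default 1.5).
#' @param stimulus_label Optional stimulus label stored on the result.
#' @return Tibble of class `"label_set"` with columns `neuron_id`, `mean_z`,
#'   `responsive`; attributes `threshold`, `stimulus_label`.
#' @examples
#' classify_responsive(tibble::tibble(neuron_id = c("a", "b"),
#'                                    mean_z = c(2.1, 0.3)))
#' @export
classify_responsive <- function(summary, threshold = 1.5,
                                stimulus_label = NULL) {
  check_columns(summary, c("neuron_id", "mean_z"), "summary")
  check_positive_scalar(threshold, "threshold")
  if (any(!is.finite(summary$mean_z))) {
    abort("`mean_z` must be finite.", class = "caensembles_parameter_error")
  }
  structure(
    tibble(neuron_id = summary$neuron_id,
           mean_z = summary$mean_z,
           responsive = summary$mean_z > threshold),
    class = c("label_set", class(tibble())),
    threshold = threshold,
    stimulus_label = stimulus_label %||% NA_character_
  )
}

#' Paired per-neuron response magnitudes for two stimuli
#'
#' Computes the post-window mean-z response magnitude of each neuron for two
#' aligned tensors (e.g. social reward vs. drug seeking) and returns the
#' pairs for neurons valid in both. The magnitude is exactly the
#' [summarize_response()] `mean_z`.
#'
#' @param tensor_a,tensor_b `"aligned_tensor"` objects over the same
#'   (registered) neuron set.
#' @inheritParams summarize_response
#' @return Tibble with columns `neuron_id`, `mag_a`, `mag_b`.
#' @examples
#' sim <- sim_ensemble_session(n_neurons = 8, seed = 1)
#' ta <- align_and_zscore(sim$traces, sim$events, stimulus = "A")
#' tb <- align_and_zscore(sim$traces, sim$events, stimulus = "B")
#' head(response_magnitudes(ta, tb))
#' @export
response_magnitudes <- function(tensor_a, tensor_b, window = c(0, 20),
                                n_trials = 4) {
  sa <- summarize_response(tensor_a, window = window, n_trials = n_trials)
  sb <- summarize_response(tensor_b, window = window, n_trials = n_trials)
  pairs <- dplyr::inner_join(
    dplyr::select(sa, "neuron_id", mag_a = "mean_z"),
    dplyr::select(sb, "neuron_id", mag_b = "mean_z"),
    by = "neuron_id"
  )
  if (nrow(pairs) == 0L) {
    abort("No neuron is valid in both tensors.",
          class = "caensembles_empty_result_error")
  }
  pairs
}
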