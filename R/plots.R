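# ggplot2 views of the main result types. These are QC plots, not figure
# reproductions.

#' @describeIn compute_dff Plot the dF/F trace, optionally shading detected
#'   transient epochs (pass the tibble from [detect_transients()] as
#'   `transients`).
#' @param object A `dff_tbl`.
#' @param transients Optional transient table to shade.
#' @param ... Unused.
#' @method autoplot dff_tbl
#' @export
autoplot.dff_tbl <- function(object, transients = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = expression(Delta * F / F)) +
    ggplot2::theme_minimal()
  if (!is.null(transients) && nrow(transients) > 0) {
    p <- p + ggplot2::geom_rect(
      data = transients,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.25
    )
  }
  p
}

#' @describeIn align_photometry Trial-averaged peri-event dF/F with an SEM
#'   ribbon and trial traces.
#' @param object An `aligned_photometry` tibble.
#' @param ... Unused.
#' @method autoplot aligned_photometry
#' @export
autoplot.aligned_photometry <- function(object, ...) {
  avg <- object |>
    dplyr::group_by(.data$rel_time_s) |>
    dplyr::summarise(
      mean_dff = mean(.data$dff),
      sem = sd(.data$dff) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$rel_time_s, y = .data$mean_dff)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_dff - .data$sem,
                                      ymax = .data$mean_dff + .data$sem),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time from event (s)", y = expression(Delta * F / F)) +
    ggplot2::theme_minimal()
}

#' @describeIn align_and_zscore Heatmap of trial-averaged z-scored activity,
#'   neurons by peri-event time.
#' @param object An `aligned_tensor`.
#' @param ... Unused.
#' @method autoplot aligned_tensor
#' @export
autoplot.aligned_tensor <- function(object, ...) {
  avg <- object |>
    dplyr::filter(.data$valid) |>
    dplyr::group_by(.data$neuron_id, .data$rel_time_s) |>
    dplyr::summarise(mean_z = mean(.data$z), .groups = "drop")
  ggplot2::ggplot(avg, ggplot2::aes(x = .data$rel_time_s, y = .data$neuron_id,
                                    fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "red",
                                  name = "z") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Time from event (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn permutation_overlap_test Histogram of the permutation null
#'   with the observed overlap fraction marked.
#' @param object An `overlap_test`.
#' @param ... Unused.
#' @method autoplot overlap_test
#' @export
autoplot.overlap_test <- function(object, ...) {
  df <- tibble(null_frac = object$null_fracs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_frac)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_both_frac,
                        color = "red", linewidth = 1) +
    ggplot2::labs(
      x = "Null double-responsive fraction",
      y = "Permutations",
      title = sprintf("Observed %.3f, one-tailed p = %.3g",
                      object$observed_both_frac, object$p_one_tailed)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn match_cells Both centroid fields with segments joining
#'   matched pairs.
#' @param object A `match_table`.
#' @param a,b The centroid tables that were matched.
#' @param ... Unused.
#' @method autoplot match_table
#' @export
autoplot.match_table <- function(object, a, b, ...) {
  seg <- object |>
    dplyr::left_join(dplyr::rename(a, id_a = "neuron_id",
                                   xa = "x_px", ya = "y_px"), by = "id_a") |>
    dplyr::left_join(dplyr::rename(b, id_b = "neuron_id",
                                   xb = "x_px", yb = "y_px"), by = "id_b")
  ggplot2::ggplot() +
    ggplot2::geom_point(data = a, ggplot2::aes(x = .data$x_px, y = .data$y_px),
                        color = "steelblue", shape = 1) +
    ggplot2::geom_point(data = b, ggplot2::aes(x = .data$x_px, y = .data$y_px),
                        color = "firebrick", shape = 4) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          color = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Plot per-region input indices
#'
#' Bar chart of group-mean input indices with SEM error bars and per-brain
#' points.
#'
#' @param index Output of [normalize_inputs()] (optionally with a `group`
#'   column).
#' @return A ggplot object.
#' @export
plot_input_index <- function(index) {
  summ <- summarize_input_index(index)
  has_group <- "group" %in% names(summ)
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$region, y = .data$mean_index))
  if (has_group) {
    p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$region,
                                            y = .data$mean_index,
                                            fill = .data$group)) +
      ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                        width = 0.7)
  } else {
    p <- p + ggplot2::geom_col(fill = "grey60", width = 0.7)
  }
  p +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_index - .data$sem_index,
                   ymax = .data$mean_index + .data$sem_index),
      width = 0.2,
      position = if (has_group) ggplot2::position_dodge(width = 0.8)
                 else "identity"
    ) +
    ggplot2::labs(x = NULL, y = "Normalized input index") +
    ggplot2::theme_minimal()
}
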