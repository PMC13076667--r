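#' Simulate a pair of cross-session centroid maps
#'
#' Places `n` cell centroids uniformly in a square field of view with a
#' minimum pairwise spacing (enforced by rejection sampling), then produces a
#' second-session map by adding isotropic Gaussian jitter to each centroid
#' and dropping a fraction of cells (cells lost to focal-plane or labeling
#' changes between sessions). Session-B rows are returned in a permuted
#' order with fresh ids, and the true A-to-B correspondence is recorded.
#'
#' @param n Number of session-A cells.
#' @param field_px Side of the square field of view, pixels (default 300,
#'   a typical downsampled miniscope field).
#' @param jitter_sd Isotropic centroid jitter between sessions, pixels.
#' @param drop_frac Fraction of cells absent from session B; the dropped
#'   count is `floor(drop_frac * n)`.
#' @param min_spacing_px Minimum pairwise centroid distance, pixels.
#' @param seed Integer seed.
#' @param max_tries Total rejection-sampling attempts before giving up.
#'
#' @return A list of class `"centroid_sim"`:
#'   * `session_a`, `session_b`: tibbles `neuron_id`, `x_px`, `y_px`;
#'   * `truth`: list with `matches` (tibble `id_a`, `id_b`).
#'
#' @examples
#' sim <- sim_centroid_pair(20, jitter_sd = 1, seed = 1)
#' nrow(sim$truth$matches)
#' @export
sim_centroid_pair <- function(n,
                              field_px = 300,
                              jitter_sd = 1,
                              drop_frac = 0,
                              min_spacing_px = 15,
                              seed = 1,
                              max_tries = 1000 * max(n, 1)) {
  check_nonneg_scalar(n, "n")
  check_positive_scalar(field_px, "field_px")
  check_nonneg_scalar(jitter_sd, "jitter_sd")
  check_fraction(drop_frac, "drop_frac")
  check_nonneg_scalar(min_spacing_px, "min_spacing_px")
  n <- as.integer(n)

  with_sim_seed(seed, {
    xs <- numeric(0)
    ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort(sprintf(
          "Could not place %d centroids with spacing >= %g px in a %g px field after %d attempts.",
          n, min_spacing_px, field_px, max_tries
        ), class = "caensembles_generation_error")
      }
      cx <- runif(1, 0, field_px)
      cy <- runif(1, 0, field_px)
      if (length(xs) == 0L ||
          min((xs - cx)^2 + (ys - cy)^2) >= min_spacing_px^2) {
        xs <- c(xs, cx)
        ys <- c(ys, cy)
      }
    }

    ids_a <- sprintf("a%03d", seq_len(n))
    session_a <- tibble(neuron_id = ids_a, x_px = xs, y_px = ys)

    n_drop <- floor(drop_frac * n)
    keep <- if (n == 0L) integer(0) else sort(sample.int(n, n - n_drop))
    n_b <- length(keep)
    perm <- if (n_b > 0L) sample.int(n_b) else integer(0)
    kept <- keep[perm]
    ids_b <- sprintf("b%03d", seq_len(n_b))
    session_b <- tibble(
      neuron_id = ids_b,
      x_px = xs[kept] + rnorm(n_b, 0, jitter_sd),
      y_px = ys[kept] + rnorm(n_b, 0, jitter_sd)
    )

    structure(
      list(
        session_a = session_a,
        session_b = session_b,
        truth = list(matches = tibble(id_a = ids_a[kept], id_b = ids_b))
      ),
      class = "centroid_sim"
    )
  })
}

#' @export
print.centroid_sim <- function(x, ...) {
  cat(sprintf("<centroid_sim> %d session-A cells, %d session-B cells\n",
              nrow(x$session_a), nrow(x$session_b)))
  invisible(x)
}
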