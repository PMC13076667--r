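#' Match cells across sessions by centroid proximity
#'
#' Simplified cross-session cell registration: pairs are mutual nearest
#' neighbors whose centroid distance does not exceed `max_dist_px`.
#' Nearest-neighbor ties are broken by smaller distance, then by
#' lexicographic id, so the matching is deterministic; each id appears in at
#' most one pair, and swapping the two inputs transposes the table. This is
#' a stand-in for footprint-based probabilistic registration toolboxes and
#' is adequate when between-session jitter is small relative to cell
#' spacing.
#'
#' An optional rigid translation correction (`align = TRUE`) estimates the
#' median displacement over provisional mutual-nearest-neighbor pairs,
#' shifts session B by it, and rematches; it is off by default because
#' same-field synthetic data (and pre-registered real data) need none.
#'
#' @param a,b Centroid tables: data frames with columns `neuron_id`, `x_px`,
#'   `y_px`.
#' @param max_dist_px Maximum allowed pair distance, pixels.
#' @param align Estimate and remove a rigid translation first?
#' @return Tibble of class `"match_table"` with columns `id_a`, `id_b`,
#'   `distance_px` (sorted by `id_a`); attributes `unmatched_a`,
#'   `unmatched_b`, `n_a`, `n_b`, `translation`.
#' @examples
#' sim <- sim_centroid_pair(20, jitter_sd = 1, seed = 1)
#' match_cells(sim$session_a, sim$session_b, max_dist_px = 5)
#' @export
match_cells <- function(a, b, max_dist_px, align = FALSE) {
  check_columns(a, c("neuron_id", "x_px", "y_px"), "a")
  check_columns(b, c("neuron_id", "x_px", "y_px"), "b")
  check_positive_scalar(max_dist_px, "max_dist_px")
  if (anyDuplicated(a$neuron_id) || anyDuplicated(b$neuron_id)) {
    abort("Duplicate neuron ids in a centroid set.",
          class = "caensembles_parameter_error")
  }
  coords <- function(df) cbind(as.numeric(df$x_px), as.numeric(df$y_px))
  pa <- coords(a)
  pb <- coords(b)
  if (any(!is.finite(pa)) || any(!is.finite(pb))) {
    abort("Centroid coordinates must be finite.",
          class = "caensembles_parameter_error")
  }

  translation <- c(dx = 0, dy = 0)
  if (align && nrow(a) > 0L && nrow(b) > 0L) {
    prov <- mnn_pairs(pa, pb, a$neuron_id, b$neuron_id, Inf)
    if (nrow(prov) > 0L) {
      ia <- match(prov$id_a, a$neuron_id)
      ib <- match(prov$id_b, b$neuron_id)
      translation <- c(dx = median(pa[ia, 1] - pb[ib, 1]),
                       dy = median(pa[ia, 2] - pb[ib, 2]))
      pb <- sweep(pb, 2, -translation)
    }
  }

  pairs <- mnn_pairs(pa, pb, a$neuron_id, b$neuron_id, max_dist_px)
  structure(pairs,
            class = c("match_table", class(tibble())),
            unmatched_a = setdiff(a$neuron_id, pairs$id_a),
            unmatched_b = setdiff(b$neuron_id, pairs$id_b),
            n_a = nrow(a), n_b = nrow(b),
            translation = translation)
}

# Mutual-nearest-neighbor pairs with deterministic tie-breaking (distance,
# then lexicographic id of the candidate).
mnn_pairs <- function(pa, pb, ids_a, ids_b, max_dist) {
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    return(tibble(id_a = character(0), id_b = character(0),
                  distance_px = numeric(0)))
  }
  d <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  nn_of_a <- apply(d, 1, function(row) {
    cand <- which(row == min(row))
    cand[order(ids_b[cand])][1]
  })
  nn_of_b <- apply(d, 2, function(col) {
    cand <- which(col == min(col))
    cand[order(ids_a[cand])][1]
  })
  ia <- which(nn_of_b[nn_of_a] == seq_len(nrow(pa)))
  ib <- nn_of_a[ia]
  dist <- d[cbind(ia, ib)]
  keep <- dist <= max_dist
  out <- tibble(id_a = ids_a[ia[keep]], id_b = ids_b[ib[keep]],
                distance_px = dist[keep])
  dplyr::arrange(out, .data$id_a)
}

#' @method tidy match_table
#' @export
tidy.match_table <- function(x, ...) as_tibble(x)

#' @method glance match_table
#' @export
glance.match_table <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_a = attr(x, "n_a"),
    n_b = attr(x, "n_b"),
    n_unmatched_a = length(attr(x, "unmatched_a")),
    n_unmatched_b = length(attr(x, "unmatched_b")),
    median_distance_px = if (nrow(x) > 0) median(x$distance_px) else NA_real_
  )
}
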