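#' Cross-tabulate two responsiveness label sets
#'
#' Counts neurons responsive to stimulus A only, B only, both, or neither,
#' over a common neuron universe. Inputs are label sets from
#' [classify_responsive()] (or any data frames with `neuron_id` and
#' `responsive`); neurons are matched by id and both sets must cover the
#' same universe.
#'
#' @param labels_a,labels_b Label sets over the same neuron universe.
#' @return Tibble of class `"overlap_counts"` with one row and columns
#'   `n_total`, `a_only`, `b_only`, `both`, `neither`.
#' @examples
#' la <- tibble::tibble(neuron_id = letters[1:4],
#'                      responsive = c(TRUE, TRUE, FALSE, FALSE))
#' lb <- tibble::tibble(neuron_id = letters[1:4],
#'                      responsive = c(TRUE, FALSE, TRUE, FALSE))
#' overlap_counts(la, lb)
#' @export
overlap_counts <- function(labels_a, labels_b) {
  check_columns(labels_a, c("neuron_id", "responsive"), "labels_a")
  check_columns(labels_b, c("neuron_id", "responsive"), "labels_b")
  if (nrow(labels_a) != nrow(labels_b) ||
      !setequal(labels_a$neuron_id, labels_b$neuron_id)) {
    abort("Label sets must cover the same neuron universe.",
          class = "caensembles_parameter_error")
  }
  rb <- labels_b$responsive[match(labels_a$neuron_id, labels_b$neuron_id)]
  ra <- labels_a$responsive
  new_overlap_counts(
    n_total = length(ra),
    a_only = sum(ra & !rb),
    b_only = sum(!ra & rb),
    both = sum(ra & rb),
    neither = sum(!ra & !rb)
  )
}

#' Build overlap counts directly from the four cells
#'
#' Convenience constructor for published contingency summaries (e.g. 84 A
#' only, 65 B only, 34 both, 197 neither out of 380).
#'
#' @param a_only,b_only,both,neither Non-negative integer cell counts.
#' @return Tibble of class `"overlap_counts"`.
#' @examples
#' make_overlap_counts(a_only = 84, b_only = 65, both = 34, neither = 197)
#' @export
make_overlap_counts <- function(a_only, b_only, both, neither) {
  for (v in list(a_only, b_only, both, neither)) check_nonneg_scalar(v, "cell")
  new_overlap_counts(n_total = a_only + b_only + both + neither,
                     a_only = a_only, b_only = b_only, both = both,
                     neither = neither)
}

new_overlap_counts <- function(n_total, a_only, b_only, both, neither) {
  stopifnot(a_only + b_only + both + neither == n_total)
  structure(
    tibble(n_total = as.integer(n_total), a_only = as.integer(a_only),
           b_only = as.integer(b_only), both = as.integer(both),
           neither = as.integer(neither)),
    class = c("overlap_counts", class(tibble()))
  )
}

#' Marginal-preserving permutation test for ensemble overlap
#'
#' Tests whether the observed number of double-responsive neurons exceeds
#' chance, given the number of neurons responsive to each stimulus. Each of
#' `n_perm` permutations independently re-draws both label sets as uniform
#' random subsets of the neuron universe with the observed margins
#' (sizes `a_only + both` and `b_only + both`) and records the fraction of
#' double-responsive neurons. The one-tailed p-value uses the add-one
#' correction \eqn{p = (1 + \#\{null \ge observed\}) / (n_{perm} + 1)}, so
#' finite permutations can never report p = 0.
#'
#' Under this global shuffle the null count of double-responsive neurons is
#' exactly hypergeometric, so [hypergeometric_tail()] provides a closed-form
#' oracle the Monte-Carlo p converges to. An optional stratified mode
#' shuffles within strata (e.g. animals), preserving per-stratum margins;
#' supply `strata` as a data frame of per-stratum counts with columns
#' `n_total`, `n_a`, `n_b` (margins including double-responsive cells).
#'
#' @param counts An `"overlap_counts"` object (or one-row data frame with
#'   `n_total`, `a_only`, `b_only`, `both`, `neither`).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the shuffle.
#' @param strata Optional per-stratum margins (see Details); when supplied,
#'   `counts` still provides the observed overlap and total.
#' @return A list of class `"overlap_test"` with elements `observed_both`,
#'   `observed_both_frac`, `null_fracs` (length `n_perm`), `p_one_tailed`,
#'   `n_perm`, `seed`, `margins`.
#' @examples
#' cnt <- make_overlap_counts(a_only = 84, b_only = 65, both = 34,
#'                            neither = 197)
#' res <- permutation_overlap_test(cnt, n_perm = 2000, seed = 17)
#' res$p_one_tailed
#' @export
permutation_overlap_test <- function(counts, n_perm = 10000, seed = 1,
                                     strata = NULL) {
  check_columns(counts, c("n_total", "a_only", "b_only", "both", "neither"),
                "counts")
  check_positive_scalar(n_perm, "n_perm")
  n_perm <- as.integer(n_perm)
  n_total <- counts$n_total[1]
  if (n_total < 1) {
    abort("`n_total` must be >= 1.", class = "caensembles_parameter_error")
  }
  k_obs <- counts$both[1]
  obs_frac <- k_obs / n_total

  if (is.null(strata)) {
    strata_tbl <- tibble(n_total = n_total,
                         n_a = counts$a_only[1] + k_obs,
                         n_b = counts$b_only[1] + k_obs)
  } else {
    check_columns(strata, c("n_total", "n_a", "n_b"), "strata")
    if (sum(strata$n_total) != n_total) {
      abort("Stratum sizes must sum to `n_total`.",
            class = "caensembles_parameter_error")
    }
    strata_tbl <- strata
  }
  if (any(strata_tbl$n_a > strata_tbl$n_total) ||
      any(strata_tbl$n_b > strata_tbl$n_total)) {
    abort("Margins cannot exceed stratum sizes.",
          class = "caensembles_parameter_error")
  }

  null_both <- with_sim_seed(seed, {
    tot <- integer(n_perm)
    for (s in seq_len(nrow(strata_tbl))) {
      ns <- strata_tbl$n_total[s]
      ka <- strata_tbl$n_a[s]
      kb <- strata_tbl$n_b[s]
      if (ka == 0L || kb == 0L) next
      for (i in seq_len(n_perm)) {
        # Independent uniform redraws of both label sets with fixed margins.
        lab_a <- sample.int(ns, ka)
        lab_b <- sample.int(ns, kb)
        tot[i] <- tot[i] + sum(tabulate(c(lab_a, lab_b), ns) == 2L)
      }
    }
    tot
  })

  null_fracs <- null_both / n_total
  p <- (1 + sum(null_fracs >= obs_frac)) / (n_perm + 1)
  structure(
    list(observed_both = k_obs,
         observed_both_frac = obs_frac,
         null_fracs = null_fracs,
         p_one_tailed = p,
         n_perm = n_perm,
         seed = seed,
         margins = strata_tbl),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> observed both = %d (%.3f), null mean = %.3f, one-tailed p = %.4g (%d permutations)\n",
    x$observed_both, x$observed_both_frac, mean(x$null_fracs),
    x$p_one_tailed, x$n_perm
  ))
  invisible(x)
}

#' @method tidy overlap_test
#' @export
tidy.overlap_test <- function(x, ...) {
  q <- stats::quantile(x$null_fracs, c(0.025, 0.5, 0.975))
  tibble(
    observed_both_frac = x$observed_both_frac,
    null_mean = mean(x$null_fracs),
    null_q025 = q[[1]], null_median = q[[2]], null_q975 = q[[3]],
    p_one_tailed = x$p_one_tailed
  )
}

#' @method glance overlap_test
#' @export
glance.overlap_test <- function(x, ...) {
  tibble(observed_both = x$observed_both,
         p_one_tailed = x$p_one_tailed,
         n_perm = x$n_perm,
         seed = x$seed)
}

#' Exact hypergeometric upper tail
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(`N`, `K`, `n`): the
#' number of shared elements between two independent uniform random subsets
#' of sizes `K` and `n` drawn from `N` items. Computed by direct summation
#' of log-binomial (log-factorial) terms, exact to ~1e-12 relative. This is
#' the closed-form oracle for the marginal-preserving label shuffle.
#'
#' @param N Universe size.
#' @param K Size of the first subset.
#' @param n Size of the second subset.
#' @param k Observed overlap.
#' @return Upper-tail probability, a single number in \[0, 1\].
#' @examples
#' hypergeometric_tail(10, 5, 5, 5)  # 1 / choose(10, 5)
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(!is.finite(vals)) || any(vals != round(vals))) {
    abort("All arguments must be finite integers.",
          class = "caensembles_parameter_error")
  }
  if (N < 0 || K < 0 || n < 0 || K > N || n > N) {
    abort("Need 0 <= K <= N and 0 <= n <= N.",
          class = "caensembles_parameter_error")
  }
  hi <- min(K, n)
  lo <- max(0, K + n - N)
  if (k <= lo) return(1)
  if (k > hi) return(0)
  j <- seq(k, hi)
  lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m) * sum(exp(lp - m)))
}

#' Pearson correlation of paired response magnitudes
#'
#' Pearson's r between the two per-neuron response magnitudes (e.g. social
#' reward vs. drug seeking) with a two-sided p-value from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}. Requires at least 3 pairs and nonzero
#' variance on both axes.
#'
#' @param pairs Data frame with columns `mag_a`, `mag_b` (one row per
#'   neuron), as returned by [response_magnitudes()].
#' @return One-row tibble: `r`, `p_value`, `n`, `conf_low`, `conf_high`
#'   (95% Fisher-z interval).
#' @examples
#' magnitude_correlation(sim_correlated_magnitudes(100, -0.5, seed = 1))
#' @export
magnitude_correlation <- function(pairs) {
  check_columns(pairs, c("mag_a", "mag_b"), "pairs")
  x <- pairs$mag_a
  y <- pairs$mag_b
  if (length(x) < 3L) {
    abort("Need at least 3 pairs.", class = "caensembles_parameter_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort("Degenerate variance on one axis.",
          class = "caensembles_degenerate_fit_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate),
         p_value = ct$p.value,
         n = length(x),
         conf_low = ct$conf.int[1],
         conf_high = ct$conf.int[2])
}

#' Change in responsive proportion between conditions
#'
#' Compares the fraction of responsive neurons before vs. after a
#' manipulation over the same registered neuron universe, with a
#' two-proportion chi-square test (no continuity correction by default).
#' Degenerate margins (both proportions 0 or both 1) are reported as
#' chi-square 0, p = 1.
#'
#' @param labels_pre,labels_post Label sets over the same neuron universe
#'   (data frames with `neuron_id`, `responsive`), or `NULL` when using the
#'   count interface.
#' @param k_pre,n_pre,k_post,n_post Count interface: responsive counts and
#'   totals for each condition (used when `labels_pre` is `NULL`).
#' @param correct Apply Yates continuity correction?
#' @return One-row tibble: `frac_pre`, `frac_post`, `chi2`, `p_value`.
#' @examples
#' proportion_change(k_pre = 50, n_pre = 100, k_post = 10, n_post = 100)
#' @export
proportion_change <- function(labels_pre = NULL, labels_post = NULL,
                              k_pre = NULL, n_pre = NULL,
                              k_post = NULL, n_post = NULL,
                              correct = FALSE) {
  if (!is.null(labels_pre)) {
    check_columns(labels_pre, c("neuron_id", "responsive"), "labels_pre")
    check_columns(labels_post, c("neuron_id", "responsive"), "labels_post")
    if (!setequal(labels_pre$neuron_id, labels_post$neuron_id)) {
      abort("Label sets must cover the same neuron universe.",
            class = "caensembles_parameter_error")
    }
    k_pre <- sum(labels_pre$responsive)
    n_pre <- nrow(labels_pre)
    k_post <- sum(labels_post$responsive)
    n_post <- nrow(labels_post)
  }
  for (v in list(k_pre, n_pre, k_post, n_post)) check_nonneg_scalar(v, "count")
  if (n_pre == 0 || n_post == 0) {
    abort("Empty neuron universe.", class = "caensembles_parameter_error")
  }
  frac_pre <- k_pre / n_pre
  frac_post <- k_post / n_post
  pooled <- (k_pre + k_post) / (n_pre + n_post)
  if (pooled == 0 || pooled == 1) {
    return(tibble(frac_pre = frac_pre, frac_post = frac_post,
                  chi2 = 0, p_value = 1))
  }
  pt <- suppressWarnings(
    stats::prop.test(c(k_pre, k_post), c(n_pre, n_post), correct = correct)
  )
  tibble(frac_pre = frac_pre, frac_post = frac_post,
         chi2 = unname(pt$statistic), p_value = pt$p.value)
}

#' Rounded percentage summary
#'
#' `round(100 * k / n)` to the nearest integer percent with half-up
#' rounding, matching how ensemble proportions are conventionally printed
#' (e.g. 84 of 380 neurons is 22%).
#'
#' @param k Numerator count(s).
#' @param n Denominator count(s), `>= 1`.
#' @return Integer percent(s).
#' @examples
#' percent_summary(84, 380)
#' percent_summary(18, 25)
#' @export
percent_summary <- function(k, n) {
  if (any(n < 1)) {
    abort("`n` must be >= 1.", class = "caensembles_parameter_error")
  }
  if (any(k < 0) || any(k > n)) {
    abort("Need 0 <= k <= n.", class = "caensembles_parameter_error")
  }
  as.integer(floor(100 * k / n + 0.5))
}
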