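# Contingency counts ----------------------------------------------------------

test_that("overlap counts cross-tabulate label sets correctly", {
  la <- tibble::tibble(neuron_id = letters[1:4],
                       responsive = c(TRUE, TRUE, FALSE, FALSE))
  lb <- tibble::tibble(neuron_id = letters[1:4],
                       responsive = c(TRUE, FALSE, TRUE, FALSE))
  cnt <- overlap_counts(la, lb)
  expect_identical(
    c(cnt$both, cnt$a_only, cnt$b_only, cnt$neither),
    c(1L, 1L, 1L, 1L)
  )
  cnt2 <- overlap_counts(la, la)
  expect_identical(cnt2$both, 2L)
  expect_identical(cnt2$a_only + cnt2$b_only, 0L)
  expect_error(overlap_counts(la, lb[1:3, ]),
               class = "caensembles_parameter_error")
})

test_that("counts are matched by id, not by row order", {
  la <- tibble::tibble(neuron_id = c("a", "b"), responsive = c(TRUE, FALSE))
  lb <- tibble::tibble(neuron_id = c("b", "a"), responsive = c(TRUE, FALSE))
  cnt <- overlap_counts(la, lb)
  expect_identical(cnt$both, 0L)
  expect_identical(cnt$a_only, 1L)
  expect_identical(cnt$b_only, 1L)
})

test_that("the four cells always sum to the total", {
  withr::with_seed(1, {
    for (i in 1:20) {
      n <- sample(1:200, 1)
      ids <- sprintf("n%03d", 1:n)
      la <- tibble::tibble(neuron_id = ids, responsive = runif(n) < runif(1))
      lb <- tibble::tibble(neuron_id = ids, responsive = runif(n) < runif(1))
      cnt <- overlap_counts(la, lb)
      expect_identical(cnt$a_only + cnt$b_only + cnt$both + cnt$neither,
                       cnt$n_total)
    }
  })
})

# Percent summaries ------------------------------------------------------------

test_that("printed ensemble percentages are reproduced from their counts", {
  expect_identical(percent_summary(84, 380), 22L)
  expect_identical(percent_summary(65, 380), 17L)
  expect_identical(percent_summary(34, 380), 9L)
  expect_identical(percent_summary(18, 25), 72L)
  expect_identical(percent_summary(0, 10), 0L)
  expect_identical(percent_summary(1, 200), 1L)  # half-up rounding of 0.5
  expect_error(percent_summary(1, 0), class = "caensembles_parameter_error")
  expect_error(percent_summary(5, 3), class = "caensembles_parameter_error")
})

# Hypergeometric oracle --------------------------------------------------------

test_that("hypergeometric tail matches a full enumeration oracle", {
  # P(X >= 5) for N = 10, K = 5, n = 5: enumerate all C(10, 5) second subsets
  # against a fixed first subset (symmetry).
  subsets <- utils::combn(10, 5)
  overlaps <- colSums(subsets <= 5)
  expect_equal(hypergeometric_tail(10, 5, 5, 5), mean(overlaps >= 5),
               tolerance = 1e-14)
  expect_equal(hypergeometric_tail(10, 5, 5, 5), 1 / choose(10, 5),
               tolerance = 1e-14)
  expect_equal(hypergeometric_tail(10, 5, 5, 3), mean(overlaps >= 3),
               tolerance = 1e-14)
})

test_that("hypergeometric tail handles boundary arguments", {
  expect_identical(hypergeometric_tail(380, 118, 99, 0), 1)
  expect_identical(hypergeometric_tail(380, 118, 99, 100), 0)
  # lower support bound: overlap can never be below K + n - N
  expect_identical(hypergeometric_tail(10, 8, 7, 5), 1)
  expect_error(hypergeometric_tail(10, 12, 5, 2),
               class = "caensembles_parameter_error")
})

test_that("hypergeometric tail agrees with the distribution in stats", {
  withr::with_seed(2, {
    for (i in 1:50) {
      N <- sample(5:400, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeometric_tail(N, K, n, k),
                   stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   tolerance = 1e-12)
    }
  })
})

# Permutation test -------------------------------------------------------------

test_that("degenerate margins give p = 1", {
  p_empty <- permutation_overlap_test(
    make_overlap_counts(0, 10, 0, 30), n_perm = 500, seed = 1
  )
  expect_identical(p_empty$p_one_tailed, 1)
  expect_true(all(p_empty$null_fracs == 0))

  p_full <- permutation_overlap_test(
    make_overlap_counts(0, 0, 40, 0), n_perm = 500, seed = 1
  )
  expect_identical(p_full$p_one_tailed, 1)
  expect_true(all(p_full$null_fracs == 1))
})

test_that("the permutation test is seed-deterministic", {
  cnt <- make_overlap_counts(84, 65, 34, 197)
  r1 <- permutation_overlap_test(cnt, n_perm = 1000, seed = 17)
  r2 <- permutation_overlap_test(cnt, n_perm = 1000, seed = 17)
  expect_identical(r1$null_fracs, r2$null_fracs)
  expect_identical(r1$p_one_tailed, r2$p_one_tailed)
})

test_that("the permutation p converges to the exact hypergeometric tail", {
  cnt <- make_overlap_counts(84, 65, 34, 197)  # N = 380, K = 118, n = 99
  res <- permutation_overlap_test(cnt, n_perm = 10000, seed = 17)
  p_exact <- hypergeometric_tail(380, 118, 99, 34)
  se <- sqrt(p_exact * (1 - p_exact) / res$n_perm)
  expect_lt(abs(res$p_one_tailed - p_exact), 3 * se)
  # null mean of the shared count is K * n / N
  expect_equal(mean(res$null_fracs) * 380, 118 * 99 / 380, tolerance = 0.1)
})

test_that("p is monotonically non-increasing in the observed overlap", {
  # margins fixed at K = 30, n = 25, N = 120; vary only the observed k
  ps <- sapply(5:25, function(k) {
    cnt <- make_overlap_counts(30 - k, 25 - k, k, 120 - 30 - 25 + k)
    permutation_overlap_test(cnt, n_perm = 2000, seed = 4)$p_one_tailed
  })
  expect_true(all(diff(ps) <= 0))
})

test_that("stratified shuffles respect per-stratum margins", {
  cnt <- make_overlap_counts(10, 10, 10, 70)
  strata <- tibble::tibble(n_total = c(50, 50), n_a = c(20, 0), n_b = c(0, 20))
  res <- permutation_overlap_test(cnt, n_perm = 500, seed = 5, strata = strata)
  # margins never co-occur within a stratum, so the null overlap is always 0
  expect_true(all(res$null_fracs == 0))
  expect_error(
    permutation_overlap_test(cnt, strata = tibble::tibble(
      n_total = 10, n_a = 5, n_b = 5
    )),
    class = "caensembles_parameter_error"
  )
})

# Magnitude correlation --------------------------------------------------------

test_that("perfect linear relations give r of +/- 1", {
  x <- rnorm(20)
  expect_equal(magnitude_correlation(tibble::tibble(mag_a = x, mag_b = x))$r, 1)
  expect_equal(magnitude_correlation(tibble::tibble(mag_a = x, mag_b = -x))$r, -1)
})

test_that("degenerate magnitude input is rejected", {
  expect_error(magnitude_correlation(tibble::tibble(mag_a = 1:2, mag_b = 2:1)),
               class = "caensembles_parameter_error")
  expect_error(
    magnitude_correlation(tibble::tibble(mag_a = rep(1, 10), mag_b = rnorm(10))),
    class = "caensembles_degenerate_fit_error"
  )
})

test_that("the t-transform p-value matches the closed form", {
  pairs <- sim_correlated_magnitudes(40, rho = -0.6, seed = 3)
  res <- magnitude_correlation(pairs)
  tstat <- res$r * sqrt((res$n - 2) / (1 - res$r^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tstat), df = res$n - 2),
               tolerance = 1e-12)
})

# Proportion change ------------------------------------------------------------

test_that("identical label sets give chi-square 0 and p 1", {
  ids <- letters[1:10]
  lab <- tibble::tibble(neuron_id = ids, responsive = rep(c(TRUE, FALSE), 5))
  res <- proportion_change(lab, lab)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
})

test_that("the two-proportion chi-square matches the hand formula", {
  res <- proportion_change(k_pre = 50, n_pre = 100, k_post = 10, n_post = 100)
  p_pool <- 60 / 200
  chi2_hand <- (0.5 - 0.1)^2 / (p_pool * (1 - p_pool) * (1 / 100 + 1 / 100))
  expect_equal(res$chi2, chi2_hand, tolerance = 1e-10)
  expect_equal(res$frac_pre, 0.5)
  expect_equal(res$frac_post, 0.1)
  expect_lt(res$p_value, 0.001)
})

test_that("zero margins are guarded", {
  res <- proportion_change(k_pre = 0, n_pre = 100, k_post = 0, n_post = 100)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
  expect_error(proportion_change(k_pre = 0, n_pre = 0, k_post = 1, n_post = 10),
               class = "caensembles_parameter_error")
})
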