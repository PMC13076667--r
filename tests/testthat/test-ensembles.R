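# z-scoring ------------------------------------------------------------------

test_that("z-scores match the hand-computed baseline statistics", {
  # fs = 2 Hz; baseline window [-2, 0) holds 4 samples set to 1, 1, 3, 3
  # (mean 2, sample SD 2/sqrt(3)); the sample 1 s after the event is 4.
  fs <- 2
  t <- (0:60) / fs
  x <- rep(2, length(t))
  ev <- 10
  x[t %in% c(8, 8.5, 9, 9.5)] <- c(1, 1, 3, 3)
  x[t == 11] <- 4
  traces <- tibble::tibble(time_s = t, n1 = x)
  tens <- align_and_zscore(traces, ev, pre_s = 8, post_s = 20)
  z_at_1s <- tens$z[tens$rel_time_s == 1]
  expect_equal(z_at_1s, (4 - 2) / (2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(z_at_1s, 1.732, tolerance = 1e-3)
})

test_that("baseline-window z has mean 0 and unit sample SD per trial", {
  sim <- sim_ensemble_session(n_neurons = 10, seed = 2)
  tens <- align_and_zscore(sim$traces, sim$events, stimulus = "A")
  base <- dplyr::filter(tens, rel_time_s >= -2, rel_time_s < 0, valid)
  stats <- base |>
    dplyr::group_by(neuron_id, trial) |>
    dplyr::summarise(m = mean(z), s = sd(z), .groups = "drop")
  expect_lt(max(abs(stats$m)), 1e-8)
  expect_lt(max(abs(stats$s - 1)), 1e-8)
})

test_that("constant traces invalidate every trial for that neuron", {
  sim <- sim_ensemble_session(n_neurons = 4, seed = 3)
  traces <- dplyr::mutate(sim$traces, n001 = 7)
  tens <- align_and_zscore(traces, sim$events, stimulus = "A")
  expect_false(any(tens$valid[tens$neuron_id == "n001"]))
  expect_true(all(is.na(tens$z[tens$neuron_id == "n001"])))
  expect_true(all(tens$valid[tens$neuron_id == "n002"]))
})

test_that("an all-constant trace matrix cannot be aligned", {
  t <- (0:900) / 15
  traces <- tibble::tibble(time_s = t, n1 = 1, n2 = 2)
  expect_error(align_and_zscore(traces, 30),
               class = "caensembles_empty_alignment_error")
})

# Response summary ------------------------------------------------------------

test_that("summary averages time within trial then the first four trials", {
  rel <- seq(0, 20, by = 0.5)
  tens <- make_tensor_1neuron(
    lapply(c(1, 2, 3, 4, 99), function(v) rep(v, length(rel))), rel
  )
  s <- summarize_response(tens)
  expect_equal(s$mean_z, 2.5)
  expect_identical(s$n_trials_used, 4)

  tens2 <- make_tensor_1neuron(list(rep(2, length(rel))), rel)
  expect_equal(summarize_response(tens2)$mean_z, 2)
})

test_that("planted responder amplitude is recovered by the mean z-score", {
  sim <- sim_ensemble_session(n_neurons = 100, frac_a_only = 0.3,
                              frac_b_only = 0, frac_both = 0,
                              response_amp_z = 3, seed = 4)
  tens <- align_and_zscore(sim$traces, sim$events, stimulus = "A")
  s <- summarize_response(tens)
  resp_ids <- sim$truth$labels$neuron_id[sim$truth$labels$responsive_a]
  expect_equal(mean(s$mean_z[s$neuron_id %in% resp_ids]), 3, tolerance = 0.2)
  expect_equal(mean(s$mean_z[!s$neuron_id %in% resp_ids]), 0, tolerance = 0.15)
})

# Classification ---------------------------------------------------------------

test_that("responsiveness uses a strict threshold", {
  s <- tibble::tibble(neuron_id = c("a", "b", "c"),
                      mean_z = c(1.5, 1.5000001, 1.4999999))
  lab <- classify_responsive(s)
  expect_identical(lab$responsive, c(FALSE, TRUE, FALSE))
})

test_that("classification is invariant to neuron order, late trials, and affine rescaling", {
  sim <- sim_ensemble_session(n_neurons = 30, n_trials_per_stim = 6, seed = 5)
  tens <- align_and_zscore(sim$traces, sim$events, stimulus = "A")
  lab <- classify_responsive(summarize_response(tens))

  # neuron order
  ids <- setdiff(names(sim$traces), "time_s")
  traces_rev <- sim$traces[c("time_s", rev(ids))]
  tens_rev <- align_and_zscore(traces_rev, sim$events, stimulus = "A")
  lab_rev <- classify_responsive(summarize_response(tens_rev))
  expect_identical(lab$responsive[match(ids, lab$neuron_id)],
                   lab_rev$responsive[match(ids, lab_rev$neuron_id)])

  # trials after the fourth do not matter: drop events 5-6
  ev4 <- dplyr::slice_head(dplyr::filter(sim$events, stimulus_label == "A"),
                           n = 4)
  tens4 <- align_and_zscore(sim$traces, ev4)
  lab4 <- classify_responsive(summarize_response(tens4))
  expect_identical(lab$responsive, lab4$responsive)

  # per-neuron positive affine rescaling of raw fluorescence
  traces_sc <- sim$traces
  for (j in seq_along(ids)) {
    traces_sc[[ids[j]]] <- traces_sc[[ids[j]]] * (0.5 + j / 10) + 3 * j
  }
  tens_sc <- align_and_zscore(traces_sc, sim$events, stimulus = "A")
  lab_sc <- classify_responsive(summarize_response(tens_sc))
  expect_identical(lab$responsive, lab_sc$responsive)
})

# Magnitude pairs --------------------------------------------------------------

test_that("identical tensors give identical magnitudes per neuron", {
  sim <- sim_ensemble_session(n_neurons = 10, seed = 6)
  tens <- align_and_zscore(sim$traces, sim$events, stimulus = "A")
  pairs <- response_magnitudes(tens, tens)
  expect_equal(pairs$mag_a, pairs$mag_b)
  expect_identical(nrow(pairs), 10L)
})

test_that("neurons invalid in one tensor are excluded from magnitude pairs", {
  sim <- sim_ensemble_session(n_neurons = 4, seed = 7)
  traces_bad <- dplyr::mutate(sim$traces, n001 = 1)
  ta <- align_and_zscore(sim$traces, sim$events, stimulus = "A")
  tb <- suppressMessages(
    align_and_zscore(traces_bad, sim$events, stimulus = "B")
  )
  pairs <- suppressMessages(response_magnitudes(ta, tb))
  expect_false("n001" %in% pairs$neuron_id)
  expect_identical(nrow(pairs), 3L)
})

test_that("planted anti-correlated amplitudes are recovered through the pipeline", {
  amps <- sim_correlated_magnitudes(129, rho = -0.5, mean_a = 3, mean_b = 3,
                                    seed = 8)
  sim <- sim_ensemble_session(
    n_neurons = 129,
    amp_pairs = tibble::tibble(amp_a = amps$mag_a, amp_b = amps$mag_b),
    seed = 8
  )
  ta <- align_and_zscore(sim$traces, sim$events, stimulus = "A")
  tb <- align_and_zscore(sim$traces, sim$events, stimulus = "B")
  pairs <- response_magnitudes(ta, tb)
  r <- magnitude_correlation(pairs)$r
  # single-sample Fisher-z 95% interval around rho = -0.5 at n = 129
  band <- tanh(atanh(-0.5) + c(-1, 1) * 1.96 / sqrt(129 - 3))
  expect_gte(r, band[1])
  expect_lte(r, band[2])
})
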