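# Isosbestic fit ------------------------------------------------------------

test_that("affine fit recovers exact proportional and offset relations", {
  x <- 100 + sin(seq(0, 10, length.out = 500))
  fit <- fit_isosbestic(make_rec(2 * x, x))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)

  fit2 <- fit_isosbestic(make_rec(x + 5, x))
  expect_equal(fit2$slope, 1, tolerance = 1e-12)
  expect_equal(fit2$intercept, 5, tolerance = 1e-9)
})

test_that("degenerate channels fall back or error as specified", {
  x <- rep(10, 200)
  expect_warning(fit <- fit_isosbestic(make_rec(x + sin(1:200), x)),
                 "intercept-only")
  expect_equal(fit$slope, 0)
  expect_equal(fit$intercept, mean(x + sin(1:200)))
  expect_error(fit_isosbestic(make_rec(rep(2, 200), rep(10, 200))),
               class = "caensembles_degenerate_fit_error")
})

# dF/F -----------------------------------------------------------------------

test_that("dF/F is identically zero when the control explains the signal", {
  x <- 100 + 5 * sin(seq(0, 20, length.out = 1000))
  d1 <- compute_dff(make_rec(x, x))
  expect_lt(max(abs(d1$dff)), 1e-12)
  d2 <- compute_dff(make_rec(2 * x, x))
  expect_lt(max(abs(d2$dff)), 1e-12)
})

test_that("a planted transient amplitude is recovered to 1e-9 without noise", {
  sim <- sim_photometry(600, event_times = c(100, 300, 500),
                        transient_amp = 0.05, artifact_amp = 0, noise_sd = 0,
                        seed = 2)
  d <- compute_dff(sim$recording)
  expect_equal(max(d$dff, na.rm = TRUE), 0.05, tolerance = 1e-9)
  # outside planted intervals the corrected trace is flat zero
  iv <- sim$truth$transient_intervals
  outside <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(iv))) {
    outside[d$time_s >= iv$onset_s[i] & d$time_s <= iv$offset_s[i]] <- FALSE
  }
  expect_lt(max(abs(d$dff[outside])), 1e-9)
})

test_that("dF/F is invariant to affine rescaling of the control channel", {
  sim <- sim_photometry(120, event_times = c(40, 80), artifact_amp = 0.05,
                        noise_sd = 0.003, seed = 4)
  rec <- sim$recording
  d0 <- compute_dff(rec)$dff
  for (ab in list(c(2, 0), c(0.5, 10), c(3, -20))) {
    rec2 <- dplyr::mutate(rec, f405 = ab[1] * f405 + ab[2])
    d1 <- compute_dff(rec2)$dff
    expect_equal(d1, d0, tolerance = 1e-10)
  }
})

# Transient detection --------------------------------------------------------

test_that("a constant trace has a degenerate baseline", {
  expect_error(detect_transients(make_dff(rep(0.5, 1000))),
               class = "caensembles_degenerate_baseline_error")
})

test_that("a 1-s pulse at 5 MADs yields exactly one epoch spanning the pulse", {
  px <- make_pulse_trace(pulse_mads = 5, seed = 11)
  tr <- detect_transients(px$dff)
  expect_identical(nrow(tr), 1L)
  expect_lte(tr$onset_s, px$pulse_onset_s)
  expect_gte(tr$offset_s, px$pulse_offset_s)
})

test_that("a pulse between the sustain and onset thresholds is not reported", {
  px <- make_pulse_trace(pulse_mads = 2.5, seed = 11)
  expect_identical(nrow(detect_transients(px$dff)), 0L)
})

test_that("pulses shorter than the minimum duration are not reported", {
  px <- make_pulse_trace(pulse_mads = 5, pulse_dur_s = 0.4, seed = 11)
  expect_identical(nrow(detect_transients(px$dff)), 0L)
})

test_that("raising a pulse's amplitude never removes its detection", {
  prev_n <- 0L
  for (amp in c(3, 4, 6, 10)) {
    px <- make_pulse_trace(pulse_mads = amp, seed = 13)
    tr <- detect_transients(px$dff)
    expect_gte(nrow(tr), max(prev_n, 1L))
    prev_n <- nrow(tr)
  }
})

test_that("detection matches planted transients on synthetic recordings", {
  sim <- sim_photometry(600, event_times = c(100, 300, 500),
                        transient_amp = 0.1, artifact_amp = 0,
                        noise_sd = 0.005, seed = 2)
  tr <- detect_transients(compute_dff(sim$recording))
  expect_identical(nrow(tr), 3L)
  expect_equal(tr$onset_s, c(100, 300, 500), tolerance = 0.5)
})

test_that("pre-event baseline mode uses only samples before the first event", {
  px <- make_pulse_trace(pulse_mads = 5, pulse_start_s = 300, n = 20000,
                         seed = 17)
  tr <- detect_transients(px$dff, baseline = "pre_event", events = 250)
  expect_identical(nrow(tr), 1L)
  expect_error(detect_transients(px$dff, baseline = "pre_event"),
               class = "caensembles_parameter_error")
})

# Alignment and quantification ----------------------------------------------

test_that("alignment produces the contracted trial-by-time shape", {
  d <- make_dff(rnorm(10000), fs = 50)
  al <- align_photometry(d, events = 100, pre_s = 10, post_s = 10)
  expect_identical(nrow(al), 20L * 50L + 1L)
  expect_identical(unique(al$trial), 1L)
  expect_equal(range(al$rel_time_s), c(-10, 10))
})

test_that("events without full window support are dropped with a message", {
  d <- make_dff(rnorm(10000), fs = 50)
  expect_message(al <- align_photometry(d, events = c(2, 100)), "Dropped 1")
  expect_identical(max(al$trial), 1L)
  expect_error(align_photometry(d, events = 2),
               class = "caensembles_empty_alignment_error")
  expect_error(align_photometry(d, events = numeric(0)),
               class = "caensembles_empty_alignment_error")
})

test_that("AUC and peak have exact closed-form values on a square pulse", {
  fs <- 50
  x <- rep(0, 10000)
  t <- (seq_along(x) - 1) / fs
  x[t >= 100 & t <= 110] <- 1           # unit pulse covering exactly [0, 10]
  al <- align_photometry(make_dff(x, fs = fs), events = 100)
  q <- quantify_auc_peak(al)
  expect_equal(q$stim_auc, 10)
  expect_equal(q$baseline_auc, 0)
  expect_equal(q$peak_dff, 1)

  al0 <- align_photometry(make_dff(rep(0, 10000), fs = fs), events = 100)
  q0 <- quantify_auc_peak(al0)
  expect_identical(c(q0$baseline_auc, q0$stim_auc, q0$peak_dff), c(0, 0, 0))
})

test_that("stimulus AUC is additive over any interior split point", {
  withr::with_seed(5, {
    rel <- (0:500) / 50
    y <- rnorm(length(rel))
    full <- pracma::trapz(rel, y)
    for (cut in sample(2:499, 20)) {
      expect_equal(pracma::trapz(rel[1:cut], y[1:cut]) +
                     pracma::trapz(rel[cut:length(rel)], y[cut:length(rel)]),
                   full, tolerance = 1e-12)
    }
  })
})

test_that("trial-averaged peak matches the planted transient amplitude", {
  ev <- c(100, 200, 300, 400)
  sim <- sim_photometry(600, event_times = ev, transient_amp = 0.08,
                        artifact_amp = 0.02, noise_sd = 0.003, seed = 6)
  al <- align_photometry(compute_dff(sim$recording), ev)
  q <- quantify_auc_peak(al)
  expect_lt(abs(mean(q$peak_dff) - 0.08), 0.02)  # peak of signal + noise
  expect_gt(mean(q$stim_auc), mean(q$baseline_auc))
})
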