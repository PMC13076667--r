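#' Simulate a single-neuron imaging session with planted responsive ensembles
#'
#' Generates a miniscope-style session: a wide trace matrix (one fluorescence
#' column per neuron, 15 Hz by default), an event list with two stimulus
#' labels ("A" and "B"), and ground-truth responsiveness labels. A planted
#' fraction of neurons responds to stimulus A only, to B only, or to both;
#' the remainder are noise-only. Counts are `floor(frac * n_neurons)` with
#' the rounding remainder assigned to "neither", so planted counts are exact
#' and deterministic for every seed.
#'
#' Responders show an event-locked waveform with instantaneous rise and
#' exponential decay (`kernel_tau`), scaled so that its *mean over the
#' post-event scoring window* (`post_window_s`, default 20 s) equals the
#' per-trial response amplitude in baseline-noise z units. The per-trial
#' amplitude is `response_amp_z` plus Gaussian trial-to-trial jitter
#' (`trial_jitter_sd`). Because amplitudes are expressed in z units of the
#' baseline noise, downstream peri-event z-scoring recovers them directly:
#' a planted responder of amplitude 3 has expected post-window mean z of 3.
#'
#' Raw traces are `baseline + sigma * (noise + response_z)`, with per-neuron
#' baseline fluorescence drawn from U(80, 120) a.u. and noise SD `sigma` set
#' to 5% of baseline; frame noise is i.i.d. Gaussian. Events of each
#' stimulus are spaced `event_spacing_s` apart (default 40 s, enough for
#' non-overlapping \[-10, +20\] s peri-event windows), A block first.
#'
#' @param n_neurons Number of neurons.
#' @param fs Sampling rate in Hz (default 15, typical after miniscope
#'   downsampling).
#' @param n_trials_per_stim Events per stimulus (default 4; must be >= 4 so
#'   the first-four-trials summary is defined).
#' @param frac_a_only,frac_b_only,frac_both Fractions of neurons responsive
#'   to A only, B only, or both; must each lie in \[0,1\] and sum to <= 1.
#'   Defaults mirror a ~17/22/9% split of selective and dual-responsive
#'   cells.
#' @param response_amp_z Mean post-window response amplitude in baseline-z
#'   units.
#' @param kernel_tau Exponential decay constant of the response waveform in
#'   seconds.
#' @param trial_jitter_sd SD of per-trial amplitude jitter, z units.
#' @param post_window_s Post-event window length the amplitude is defined
#'   over, seconds.
#' @param event_spacing_s Spacing between consecutive events, seconds.
#' @param amp_pairs Optional tibble/data frame with columns `amp_a`, `amp_b`
#'   (one row per neuron). When supplied it overrides the fraction-based
#'   labels: every neuron responds to both stimuli with these mean
#'   amplitudes (may be negative or zero), which is useful for planting a
#'   known across-neuron correlation between response magnitudes.
#' @param seed Integer seed.
#'
#' @return A list of class `"ensemble_sim"`:
#'   * `traces`: wide tibble, `time_s` plus one column per neuron;
#'   * `events`: tibble `onset_s`, `stimulus_label` ("A"/"B");
#'   * `truth`: list with `labels` (tibble `neuron_id`, `responsive_a`,
#'     `responsive_b`), and when `amp_pairs` is used, the planted `amp_pairs`.
#'
#' @examples
#' sim <- sim_ensemble_session(n_neurons = 20, seed = 1)
#' dplyr::count(sim$truth$labels, responsive_a, responsive_b)
#' @export
sim_ensemble_session <- function(n_neurons,
                                 fs = 15,
                                 n_trials_per_stim = 4,
                                 frac_a_only = 0.17,
                                 frac_b_only = 0.22,
                                 frac_both = 0.09,
                                 response_amp_z = 3,
                                 kernel_tau = 6,
                                 trial_jitter_sd = 0.5,
                                 post_window_s = 20,
                                 event_spacing_s = 40,
                                 amp_pairs = NULL,
                                 seed = 1) {
  check_positive_scalar(n_neurons, "n_neurons")
  check_positive_scalar(fs, "fs")
  check_positive_scalar(kernel_tau, "kernel_tau")
  check_nonneg_scalar(trial_jitter_sd, "trial_jitter_sd")
  check_positive_scalar(post_window_s, "post_window_s")
  check_positive_scalar(event_spacing_s, "event_spacing_s")
  check_fraction(frac_a_only, "frac_a_only")
  check_fraction(frac_b_only, "frac_b_only")
  check_fraction(frac_both, "frac_both")
  if (frac_a_only + frac_b_only + frac_both > 1 + 1e-12) {
    abort("`frac_a_only + frac_b_only + frac_both` must not exceed 1.",
          class = "caensembles_parameter_error")
  }
  if (n_trials_per_stim < 4) {
    abort("`n_trials_per_stim` must be at least 4.",
          class = "caensembles_parameter_error")
  }
  n_neurons <- as.integer(n_neurons)
  n_trials <- as.integer(n_trials_per_stim)

  ids <- sprintf("n%03d", seq_len(n_neurons))

  with_sim_seed(seed, {
    # Planted labels: exact floor counts, remainder -> neither; which neurons
    # get which label is a seeded permutation so labels are not tied to id
    # order.
    if (is.null(amp_pairs)) {
      n_a <- floor(frac_a_only * n_neurons)
      n_b <- floor(frac_b_only * n_neurons)
      n_ab <- floor(frac_both * n_neurons)
      assign <- rep("neither", n_neurons)
      perm <- sample.int(n_neurons)
      assign[perm[seq_len(n_a)]] <- "a_only"
      if (n_b > 0) assign[perm[n_a + seq_len(n_b)]] <- "b_only"
      if (n_ab > 0) assign[perm[n_a + n_b + seq_len(n_ab)]] <- "both"
      resp_a <- assign %in% c("a_only", "both")
      resp_b <- assign %in% c("b_only", "both")
      amp_a <- ifelse(resp_a, response_amp_z, 0)
      amp_b <- ifelse(resp_b, response_amp_z, 0)
    } else {
      check_columns(amp_pairs, c("amp_a", "amp_b"), "amp_pairs")
      if (nrow(amp_pairs) != n_neurons) {
        abort("`amp_pairs` must have one row per neuron.",
              class = "caensembles_parameter_error")
      }
      amp_a <- as.numeric(amp_pairs$amp_a)
      amp_b <- as.numeric(amp_pairs$amp_b)
      resp_a <- amp_a > 0
      resp_b <- amp_b > 0
    }

    # Event schedule: A block then B block.
    first <- 30
    onsets_a <- first + (seq_len(n_trials) - 1) * event_spacing_s
    onsets_b <- max(onsets_a) + event_spacing_s +
      (seq_len(n_trials) - 1) * event_spacing_s
    duration_s <- max(onsets_b) + event_spacing_s
    n_frames <- as.integer(round(duration_s * fs))
    t <- seq_len(n_frames) / fs - 1 / fs

    # Response kernel in z units, normalised to unit mean over the
    # post-event scoring window.
    kernel_mean <- kernel_tau * (1 - exp(-post_window_s / kernel_tau)) /
      post_window_s
    add_response <- function(zmat_col, onsets, amp_mean) {
      if (amp_mean == 0) return(zmat_col)
      for (te in onsets) {
        amp_trial <- amp_mean + rnorm(1) * trial_jitter_sd
        i0 <- as.integer(ceiling(te * fs)) + 1L
        i1 <- min(n_frames, as.integer(floor((te + post_window_s) * fs)) + 1L)
        if (i0 <= i1) {
          dt <- t[i0:i1] - te
          zmat_col[i0:i1] <- zmat_col[i0:i1] +
            amp_trial * exp(-dt / kernel_tau) / kernel_mean
        }
      }
      zmat_col
    }

    baseline_f <- runif(n_neurons, 80, 120)
    sigma <- 0.05 * baseline_f
    traces <- matrix(0, nrow = n_frames, ncol = n_neurons)
    for (j in seq_len(n_neurons)) {
      z <- rnorm(n_frames)
      z <- add_response(z, onsets_a, amp_a[j])
      z <- add_response(z, onsets_b, amp_b[j])
      traces[, j] <- baseline_f[j] + sigma[j] * z
    }
    colnames(traces) <- ids

    out <- list(
      traces = dplyr::bind_cols(tibble(time_s = t), as_tibble(traces)),
      events = tibble(
        onset_s = c(onsets_a, onsets_b),
        stimulus_label = rep(c("A", "B"), each = n_trials)
      ),
      truth = list(
        labels = tibble(neuron_id = ids,
                        responsive_a = resp_a,
                        responsive_b = resp_b)
      )
    )
    if (!is.null(amp_pairs)) {
      out$truth$amp_pairs <- tibble(neuron_id = ids,
                                    amp_a = amp_a, amp_b = amp_b)
    }
    structure(out, class = "ensemble_sim")
  })
}

#' @export
print.ensemble_sim <- function(x, ...) {
  cat(sprintf(
    "<ensemble_sim> %d neurons x %d frames, %d events\n",
    ncol(x$traces) - 1L, nrow(x$traces), nrow(x$events)
  ))
  invisible(x)
}

#' Simulate correlated response-magnitude pairs
#'
#' Draws per-neuron (magnitude to stimulus A, magnitude to stimulus B) pairs
#' from a bivariate normal with unit variances and correlation `rho`. Used to
#' validate the Pearson magnitude-correlation estimator against its
#' closed-form (Fisher-z) sampling distribution.
#'
#' @param n Number of neurons (pairs).
#' @param rho Planted population correlation, in (-1, 1).
#' @param mean_a,mean_b Means of the two magnitudes (z units).
#' @param seed Integer seed.
#' @return Tibble with columns `neuron_id`, `mag_a`, `mag_b`.
#' @examples
#' pairs <- sim_correlated_magnitudes(100, rho = -0.5, seed = 1)
#' cor(pairs$mag_a, pairs$mag_b)
#' @export
sim_correlated_magnitudes <- function(n, rho, mean_a = 0, mean_b = 0, seed = 1) {
  check_positive_scalar(n, "n")
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1) {
    abort("`rho` must be a single number in (-1, 1).",
          class = "caensembles_parameter_error")
  }
  with_sim_seed(seed, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    tibble(
      neuron_id = sprintf("n%03d", seq_len(as.integer(n))),
      mag_a = mean_a + x,
      mag_b = mean_b + y
    )
  })
}
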