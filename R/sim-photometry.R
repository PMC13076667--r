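#' Simulate a two-channel fiber-photometry recording
#'
#' Generates a paired 470-nm (calcium-sensitive) and 405-nm (isosbestic
#' control) recording with known ground truth. Both channels share a slow
#' photobleaching decay and a multiplicative motion artifact (slow sinusoids
#' plus a scaled random walk); only the 470 channel carries event-locked
#' calcium transients. This mirrors the physical model that makes isosbestic
#' regression a valid artifact correction: with zero sensor noise and no
#' transients the two channels are related by an exact affine map, so the
#' corrected dF/F is identically zero.
#'
#' The signal model is
#' \deqn{F_{470}(t) = B_{470}\, b(t)\,[1 + a(t) + s(t)] + \epsilon_{470}(t)}
#' \deqn{F_{405}(t) = B_{405}\, b(t)\,[1 + a(t)] + \epsilon_{405}(t)}
#' with bleach \eqn{b(t) = e^{-t/\tau_b}}, shared artifact \eqn{a(t)}, and
#' transient term \eqn{s(t)} a sum of instantaneous-rise, exponential-decay
#' kernels of peak amplitude `transient_amp` (in dF/F units) at each event
#' onset. Additive sensor noise has standard deviation `noise_sd` expressed
#' as a fraction of each channel's baseline.
#'
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz (default 50, the rate of typical
#'   multi-channel photometry systems).
#' @param event_times Numeric vector of transient onset times in seconds;
#'   all must lie in `[0, duration_s)`.
#' @param transient_amp Peak transient amplitude in dF/F units.
#' @param decay_tau Transient exponential decay constant in seconds
#'   (default 1.5, a GCaMP6s-like decay).
#' @param artifact_amp Amplitude of the shared multiplicative artifact, as a
#'   fraction of baseline.
#' @param bleach_tau Photobleaching time constant in seconds; `Inf` disables
#'   bleaching.
#' @param noise_sd Additive sensor noise SD as a fraction of baseline
#'   (i.e. in dF/F units).
#' @param baseline_470,baseline_405 Baseline fluorescence of each channel in
#'   arbitrary units.
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#'
#' @return A list of class `"photometry_sim"` with elements
#'   * `recording`: tibble with columns `time_s`, `f470`, `f405`;
#'   * `truth`: list with `transient_intervals` (tibble `onset_s`,
#'     `offset_s`, non-overlapping and ordered), `transient_amp`, and the
#'     noiseless `dff_true` vector (the transient term itself).
#'
#' @examples
#' sim <- sim_photometry(60, event_times = c(20, 40), seed = 1)
#' head(sim$recording)
#' sim$truth$transient_intervals
#' @export
sim_photometry <- function(duration_s = 600,
                           fs = 50,
                           event_times = numeric(0),
                           transient_amp = 0.05,
                           decay_tau = 1.5,
                           artifact_amp = 0.05,
                           bleach_tau = 1200,
                           noise_sd = 0.002,
                           baseline_470 = 200,
                           baseline_405 = 120,
                           seed = 1) {
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(fs, "fs")
  check_positive_scalar(decay_tau, "decay_tau")
  check_nonneg_scalar(transient_amp, "transient_amp")
  check_nonneg_scalar(artifact_amp, "artifact_amp")
  check_nonneg_scalar(noise_sd, "noise_sd")
  check_positive_scalar(baseline_470, "baseline_470")
  check_positive_scalar(baseline_405, "baseline_405")
  if (!(is.numeric(bleach_tau) && length(bleach_tau) == 1L && bleach_tau > 0)) {
    abort("`bleach_tau` must be a single positive number (Inf allowed).",
          class = "caensembles_parameter_error")
  }
  event_times <- sort(as.numeric(event_times))
  if (length(event_times) > 0 &&
      (any(!is.finite(event_times)) || any(event_times < 0) ||
       any(event_times >= duration_s))) {
    abort("All `event_times` must lie in [0, duration_s).",
          class = "caensembles_parameter_error")
  }

  with_sim_seed(seed, {
    n <- as.integer(round(duration_s * fs))
    t <- seq_len(n) / fs - 1 / fs

    bleach <- if (is.finite(bleach_tau)) exp(-t / bleach_tau) else rep(1, n)

    # Shared artifact: two slow sinusoids plus a random walk, all scaled by
    # artifact_amp. Drawn even when artifact_amp == 0 so the RNG stream (and
    # hence the noise draws below) depends only on n, not on amplitudes.
    ph <- runif(2, 0, 2 * pi)
    fr <- runif(2, 0.005, 0.05)
    sine_part <- 0.6 * sin(2 * pi * fr[1] * t + ph[1]) +
      0.4 * sin(2 * pi * fr[2] * t + ph[2])
    rw <- cumsum(rnorm(n))
    rw <- rw - mean(rw)
    rw_sd <- sd(rw)
    if (rw_sd > 0) rw <- rw / rw_sd
    artifact <- artifact_amp * (0.7 * sine_part + 0.3 * rw)

    # Transient term: instantaneous rise, exponential decay, kernel truncated
    # where it falls below 1e-10 of its peak (so samples outside transient
    # support are exactly zero).
    transient <- rep(0, n)
    support_s <- decay_tau * log(1e10)
    for (te in event_times) {
      i0 <- as.integer(ceiling(te * fs)) + 1L
      i1 <- min(n, as.integer(floor((te + support_s) * fs)) + 1L)
      if (i0 <= i1) {
        dt <- t[i0:i1] - te
        transient[i0:i1] <- transient[i0:i1] + transient_amp * exp(-dt / decay_tau)
      }
    }

    f470 <- baseline_470 * bleach * (1 + artifact + transient) +
      noise_sd * baseline_470 * rnorm(n)
    f405 <- baseline_405 * bleach * (1 + artifact) +
      noise_sd * baseline_405 * rnorm(n)

    intervals <- tibble(
      onset_s  = event_times,
      offset_s = pmin(event_times + support_s, duration_s)
    )
    intervals <- merge_intervals(intervals)

    structure(
      list(
        recording = tibble(time_s = t, f470 = f470, f405 = f405),
        truth = list(
          transient_intervals = intervals,
          transient_amp = transient_amp,
          dff_true = transient
        )
      ),
      class = "photometry_sim"
    )
  })
}

# Merge overlapping (onset_s, offset_s) intervals into a non-overlapping,
# ordered set.
merge_intervals <- function(intervals) {
  if (nrow(intervals) <= 1L) return(intervals)
  intervals <- dplyr::arrange(intervals, .data$onset_s)
  on <- intervals$onset_s
  off <- intervals$offset_s
  keep_on <- on[1]
  keep_off <- off[1]
  for (i in seq(2L, length(on))) {
    if (on[i] <= keep_off[length(keep_off)]) {
      keep_off[length(keep_off)] <- max(keep_off[length(keep_off)], off[i])
    } else {
      keep_on <- c(keep_on, on[i])
      keep_off <- c(keep_off, off[i])
    }
  }
  tibble(onset_s = keep_on, offset_s = keep_off)
}

#' @export
print.photometry_sim <- function(x, ...) {
  rec <- x$recording
  cat(sprintf(
    "<photometry_sim> %d samples, %.1f s, %d planted transient interval(s)\n",
    nrow(rec), max(rec$time_s) + rec$time_s[2] - rec$time_s[1],
    nrow(x$truth$transient_intervals)
  ))
  invisible(x)
}
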