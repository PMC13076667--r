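# Shared fixture builders. Everything is generated in code; no files.

# A minimal two-channel recording from explicit channel vectors on a uniform
# 50 Hz grid.
make_rec <- function(f470, f405, fs = 50) {
  n <- length(f470)
  tibble::tibble(time_s = (seq_len(n) - 1) / fs, f470 = f470, f405 = f405)
}

# A dff table from an explicit dff vector (bypasses the isosbestic fit).
make_dff <- function(dff, fs = 50) {
  n <- length(dff)
  structure(
    tibble::tibble(time_s = (seq_len(n) - 1) / fs, dff = dff),
    class = c("dff_tbl", class(tibble::tibble())),
    fit_slope = 1, fit_intercept = 0, fs = fs
  )
}

# A long-format aligned tensor from a per-trial list of (rel_time, z)
# matrices for a single neuron; used for hand-computed summaries.
make_tensor_1neuron <- function(trial_z, rel_time) {
  rows <- lapply(seq_along(trial_z), function(tr) {
    tibble::tibble(neuron_id = "n1", trial = tr, rel_time_s = rel_time,
                   z = trial_z[[tr]], valid = TRUE)
  })
  structure(dplyr::bind_rows(rows),
            class = c("aligned_tensor", class(tibble::tibble())))
}

# Gaussian-noise dff trace with a clean plateau pulse at `pulse_mads` raw
# MADs above the baseline median (pulse replaces, not adds to, the noise so
# the epoch is a single uninterrupted run).
make_pulse_trace <- function(n = 20000, fs = 50, pulse_mads = 5,
                             pulse_start_s = 100, pulse_dur_s = 1, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    med <- median(x)
    madv <- median(abs(x - med))
    i0 <- as.integer(pulse_start_s * fs) + 1L
    i1 <- i0 + as.integer(pulse_dur_s * fs) - 1L
    x[i0:i1] <- med + pulse_mads * madv
    list(dff = make_dff(x, fs = fs), i0 = i0, i1 = i1,
         pulse_onset_s = (i0 - 1) / fs, pulse_offset_s = (i1 - 1) / fs)
  })
}
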