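# Internal helpers shared across modules.

# Scalar validation: positive finite number.
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "caensembles_parameter_error")
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative finite number.", name),
          class = "caensembles_parameter_error")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name),
          class = "caensembles_parameter_error")
  }
  invisible(x)
}

# Run `expr` under a locally-seeded RNG without disturbing the caller's RNG
# state. All simulation entry points funnel through this so a given seed is
# reproducible regardless of the surrounding session.
with_sim_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite integer.",
          class = "caensembles_parameter_error")
  }
  withr::with_seed(as.integer(seed), expr)
}

# Columns required in a data frame, with a friendly error.
check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", name),
          class = "caensembles_parameter_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("`%s` is missing column(s): %s.", name,
                  paste0("`", missing, "`", collapse = ", ")),
          class = "caensembles_parameter_error")
  }
  invisible(df)
}

# Sampling rate implied by a uniform time grid; errors if the grid is not
# uniform to within `rel_tol` relative tolerance.
infer_fs <- function(time_s, rel_tol = 1e-6) {
  if (length(time_s) < 2L) {
    abort("Need at least 2 samples to infer a sampling rate.",
          class = "caensembles_parameter_error")
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    abort("`time_s` must be strictly increasing.",
          class = "caensembles_parameter_error")
  }
  dt0 <- median(dt)
  if (max(abs(dt - dt0)) > rel_tol * dt0) {
    abort("`time_s` is not uniformly sampled.",
          class = "caensembles_parameter_error")
  }
  1 / dt0
}
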