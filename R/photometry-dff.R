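#' Fit the isosbestic control channel to the signal channel
#'
#' Least-squares affine fit of the 405-nm isosbestic control onto the 470-nm
#' calcium-sensitive channel, the standard correction for motion and
#' photobleaching artifacts shared by both channels. By default the fit is
#' robustified by iterative trimming: after each pass, samples whose
#' residual lies more than `trim_mads` (scaled) MADs from the median residual
#' are excluded and the fit recomputed, until the kept set stabilizes.
#' Calcium transients live only in the signal channel, so trimming removes
#' their leverage on the fit; in the noise-free limit the fitted control then
#' matches the artifact component of the signal channel exactly. Set
#' `trim_mads = Inf` for a plain ordinary-least-squares fit on all samples.
#'
#' A constant control channel (zero variance) degenerates to an
#' intercept-only fit (slope 0, intercept = mean of the signal channel) with
#' a warning; if both channels are constant the fit is undefined and an
#' error of class `"caensembles_degenerate_fit_error"` is raised.
#'
#' @param rec Data frame with columns `time_s`, `f470`, `f405`
#'   (a two-channel recording, as produced by [sim_photometry()] or
#'   [read_photometry_csv()]).
#' @param trim_mads Trimming threshold in scaled-MAD units of the residuals;
#'   `Inf` disables trimming.
#' @param max_iter Maximum trimming passes.
#' @return One-row tibble with columns `slope`, `intercept`, `n_used` (samples
#'   in the final fit), `n_iter`.
#' @examples
#' rec <- sim_photometry(60, noise_sd = 0, transient_amp = 0, seed = 1)$recording
#' fit_isosbestic(rec)
#' @export
fit_isosbestic <- function(rec, trim_mads = 5, max_iter = 20) {
  check_columns(rec, c("time_s", "f470", "f405"), "rec")
  check_positive_scalar(if (is.infinite(trim_mads)) 1 else trim_mads, "trim_mads")
  x <- as.numeric(rec$f405)
  y <- as.numeric(rec$f470)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2L) {
    abort("Need at least 2 finite samples to fit.",
          class = "caensembles_degenerate_fit_error")
  }

  if (var(x) == 0) {
    if (var(y) == 0) {
      abort("Both channels are constant; affine fit is undefined.",
            class = "caensembles_degenerate_fit_error")
    }
    warn("Control channel is constant; falling back to intercept-only fit.")
    return(tibble(slope = 0, intercept = mean(y), n_used = length(x),
                  n_iter = 1L))
  }

  ols <- function(keep) {
    xs <- x[keep]
    ys <- y[keep]
    if (length(xs) < 2L || var(xs) == 0) return(NULL)
    slope <- stats::cov(xs, ys) / var(xs)
    c(slope = slope, intercept = mean(ys) - slope * mean(xs))
  }

  keep <- rep(TRUE, length(x))
  co <- ols(keep)
  iter <- 1L
  if (is.finite(trim_mads)) {
    # Trim floor keeps the iteration from chasing floating-point noise once
    # the fit is exact on the kept samples.
    tol_floor <- 1e-12 * median(abs(y))
    repeat {
      if (iter >= max_iter) break
      resid <- y - (co["slope"] * x + co["intercept"])
      med <- median(resid[keep])
      tol <- max(trim_mads * mad(resid[keep], center = med), tol_floor)
      new_keep <- abs(resid - med) <= tol
      if (mean(new_keep) < 0.5) break        # refuse to trim away the trace
      if (identical(new_keep, keep)) break
      co2 <- ols(new_keep)
      if (is.null(co2)) break
      keep <- new_keep
      co <- co2
      iter <- iter + 1L
    }
  }

  tibble(slope = unname(co["slope"]), intercept = unname(co["intercept"]),
         n_used = sum(keep), n_iter = iter)
}

#' Compute isosbestic-corrected dF/F
#'
#' Applies the fitted-control correction
#' \deqn{\Delta F/F(t) = \frac{F_{470}(t) - \hat F_{405}(t)}{\hat F_{405}(t)}}
#' where \eqn{\hat F_{405} = a\,F_{405} + b} is the affine fit from
#' [fit_isosbestic()]. Samples where the fitted control is non-positive are
#' undefined (`NA`); if more than 1% of samples are undefined the fit is
#' considered unusable and an error of class
#' `"caensembles_fit_quality_error"` is raised.
#'
#' The result is invariant to affine rescaling of the control channel
#' (`alpha * f405 + beta`, `alpha > 0`): the fit absorbs the change.
#'
#' @inheritParams fit_isosbestic
#' @param fit Optional precomputed fit (one-row data frame with `slope`,
#'   `intercept`); when `NULL` it is computed from `rec`.
#' @return A tibble of class `"dff_tbl"` with columns `time_s`, `dff`, and
#'   attributes `fit_slope`, `fit_intercept`, `fs`.
#' @examples
#' sim <- sim_photometry(120, event_times = 60, noise_sd = 0,
#'                       artifact_amp = 0, seed = 1)
#' dff <- compute_dff(sim$recording)
#' max(dff$dff)
#' @export
compute_dff <- function(rec, fit = NULL, trim_mads = 5, max_iter = 20) {
  check_columns(rec, c("time_s", "f470", "f405"), "rec")
  if (is.null(fit)) {
    fit <- fit_isosbestic(rec, trim_mads = trim_mads, max_iter = max_iter)
  } else {
    check_columns(fit, c("slope", "intercept"), "fit")
  }
  fs <- infer_fs(rec$time_s)
  fitted <- fit$slope[1] * rec$f405 + fit$intercept[1]
  bad <- !is.finite(fitted) | fitted <= 0
  if (mean(bad) > 0.01) {
    abort(sprintf(
      "Fitted control is non-positive for %.1f%% of samples (> 1%%); fit unusable.",
      100 * mean(bad)
    ), class = "caensembles_fit_quality_error")
  }
  dff <- (rec$f470 - fitted) / fitted
  dff[bad] <- NA_real_
  new_dff_tbl(tibble(time_s = rec$time_s, dff = dff),
              fit_slope = fit$slope[1], fit_intercept = fit$intercept[1],
              fs = fs)
}

new_dff_tbl <- function(df, fit_slope, fit_intercept, fs) {
  structure(df,
            class = c("dff_tbl", class(tibble())),
            fit_slope = fit_slope,
            fit_intercept = fit_intercept,
            fs = fs)
}

#' @method glance dff_tbl
#' @export
glance.dff_tbl <- function(x, ...) {
  tibble(
    n = nrow(x),
    fs = attr(x, "fs"),
    fit_slope = attr(x, "fit_slope"),
    fit_intercept = attr(x, "fit_intercept"),
    n_undefined = sum(!is.finite(x$dff))
  )
}
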