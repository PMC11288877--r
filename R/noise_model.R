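# ---------------------------------------------------------------------------
# Background activity: brown (1/f^2) noise projected from many spatially
# dispersed sources.
# ---------------------------------------------------------------------------

#' Brown-noise background specification
#'
#' Defaults: 80 sources at least 25 mm apart, per-source per-epoch amplitude
#' 37.5 +- 0.5 microvolts (uniform bound), where "amplitude" means the
#' maximum absolute value of the scaled source waveform.
#' @param amplitude_uv target max-abs amplitude per source per epoch.
#' @param amplitude_dev_uv uniform deviation bound around `amplitude_uv`.
#' @param n_sources number of noise sources.
#' @param min_spacing_mm minimum pairwise source distance.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(amplitude_uv = 37.5, amplitude_dev_uv = 0.5,
                       n_sources = 80, min_spacing_mm = 25) {
  stopifnot(amplitude_uv > 0, n_sources >= 1)
  structure(list(color = "brown", amplitude_uv = amplitude_uv,
                 amplitude_dev_uv = amplitude_dev_uv, n_sources = n_sources,
                 min_spacing_mm = min_spacing_mm), class = "noise_spec")
}

#' Generate unit-scale brown noise
#'
#' Cumulative sum of white Gaussian increments, linearly detrended (hence
#' zero-mean); its power spectral density falls off as 1/f^2.
#' @param n_samples number of samples (>= 16).
#' @return numeric vector.
#' @export
brown_noise <- function(n_samples) {
  stopifnot(n_samples >= 16)
  w <- cumsum(stats::rnorm(n_samples))
  t <- seq_len(n_samples)
  # remove the least-squares linear trend
  fit <- stats::lm.fit(cbind(1, t), w)
  fit$residuals
}

# detrend the columns of a matrix (shared by the vectorized simulator path)
.detrend_columns <- function(M) {
  t <- seq_len(nrow(M))
  X <- cbind(1, t)
  Q <- qr.Q(qr(X))
  M - Q %*% (t(Q) %*% M)
}

#' Rescale a waveform to a randomized max-abs amplitude
#'
#' The target is drawn uniformly in
#' `[amplitude_uv - amplitude_dev_uv, amplitude_uv + amplitude_dev_uv]` and
#' the waveform is rescaled so its maximum absolute value equals the target.
#' @param waveform non-constant numeric vector.
#' @param amplitude_uv nominal amplitude.
#' @param amplitude_dev_uv uniform deviation bound.
#' @return rescaled waveform.
#' @export
scale_to_amplitude <- function(waveform, amplitude_uv,
                               amplitude_dev_uv = 0) {
  m <- max(abs(waveform))
  if (m < 1e-12)
    stop("cannot scale a constant (zero-range) waveform", call. = FALSE)
  target <- stats::runif(1, amplitude_uv - amplitude_dev_uv,
                         amplitude_uv + amplitude_dev_uv)
  waveform * (target / m)
}

#' Calibrate the scalar noise gain against decoding difficulty
#'
#' The spherical head model is not the same forward model as a realistic
#' anatomical lead field, so the absolute signal-to-noise ratio of the
#' projected data is fixed by a documented calibration rather than taken on
#' faith: a grid of `noise_gain` values is scanned and, for each, one subject
#' subjects are simulated at the given configuration and evaluated with the
#' subject-specific repeated cross-validation pipeline; the gain whose mean
#' balanced accuracy is closest to `target_bacc` is returned.  Several
#' calibration subjects are averaged because the subject-level spread of
#' balanced accuracy is a few percentage points, which would otherwise
#' dominate the calibration.  Classification difficulty, not absolute
#' microvolt level, is the quantity the downstream analyses depend on.
#'
#' @param gains candidate noise gains.
#' @param cfg a [sim_config()]; its `noise_gain` is overridden per candidate.
#' @param lf lead field (built from `cfg` if `NULL`).
#' @param target_bacc calibration target for subject-specific balanced
#'   accuracy.
#' @param eval_cfg evaluation settings passed to
#'   [evaluate_subject_specific()].
#' @param seed base seed; calibration subjects use `seed`, `seed + 1`, ...
#' @param n_subjects number of calibration subjects averaged per gain.
#' @return list with `noise_gain` (selected), and `table` of gain vs mean
#'   bACC.
#' @export
calibrate_noise_gain <- function(gains = c(0.1, 0.15, 0.2, 0.25, 0.3, 0.5, 1),
                                 cfg = sim_config(), lf = NULL,
                                 target_bacc = 0.82,
                                 eval_cfg = eval_config(n_repeats = 2),
                                 seed = 99, n_subjects = 3) {
  if (is.null(lf))
    lf <- build_spherical_leadfield(cfg$montage,
                                    n_sources = cfg$n_lf_sources,
                                    seed = seed)
  bacc <- numeric(length(gains))
  for (i in seq_along(gains)) {
    cfg_i <- cfg
    cfg_i$noise_gain <- gains[i]
    bacc[i] <- mean(vapply(seq_len(n_subjects), function(k) {
      subj <- simulate_subject(cfg_i, lf, subject_seed = seed + k - 1)
      evaluate_subject_specific(subj, eval_cfg)$mean_bacc
    }, numeric(1)))
  }
  pick <- which.min(abs(bacc - target_bacc))
  list(noise_gain = gains[pick],
       table = data.frame(noise_gain = gains, bacc = bacc))
}
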