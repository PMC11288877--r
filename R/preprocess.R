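# ---------------------------------------------------------------------------
# Preprocessing chain bringing continuous recordings to the same epoch
# representation as simulated data: downsampling, zero-phase FIR filtering,
# bad-channel interpolation, common-average reference, epoching.
# ---------------------------------------------------------------------------

#' Continuous EEG container
#'
#' @param data channels x samples matrix, microvolts.
#' @param srate sampling rate, Hz.
#' @param channel_labels montage labels (one per row).
#' @param events data.frame with columns `sample` (1-based index) and
#'   `label`.
#' @return object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(data, srate, channel_labels,
                           events = data.frame(sample = integer(),
                                               label = character())) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_labels))
  if (!all(is.finite(data)))
    stop("continuous data contains non-finite values", call. = FALSE)
  if (nrow(events) && (any(events$sample < 1) ||
                         any(events$sample > ncol(data))))
    stop("event sample indices out of bounds", call. = FALSE)
  structure(list(data = data, srate = srate,
                 channel_labels = channel_labels, events = events),
            class = "continuous_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("<continuous_eeg> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$srate, nrow(x$events)))
  invisible(x)
}

#' Downsample a continuous recording
#'
#' Integer-factor downsampling uses a zero-phase anti-alias FIR low-pass
#' (Hamming sinc, cutoff at 80% of the new Nyquist frequency) followed by
#' decimation; non-integer rate ratios fall back to polyphase resampling.
#' Event indices are rescaled and rounded to the nearest sample.  Upsampling
#' requests are refused.
#' @param eeg a [continuous_eeg()].
#' @param target_srate target rate, Hz (must not exceed the current rate).
#' @return resampled [continuous_eeg()].
#' @export
resample_eeg <- function(eeg, target_srate = 250) {
  if (target_srate > eeg$srate)
    stop("upsampling not supported (target rate above recording rate)",
         call. = FALSE)
  if (target_srate == eeg$srate) return(eeg)
  ratio <- eeg$srate / target_srate
  if (abs(ratio - round(ratio)) < 1e-9) {
    q <- round(ratio)
    cutoff <- 0.8 * target_srate / 2
    b <- signal::fir1(.fir_order(0.2 * target_srate / 2, eeg$srate),
                      cutoff / (eeg$srate / 2))
    out <- t(apply(eeg$data, 1, function(x) {
      signal::filtfilt(signal::Ma(b), x)[seq(1, length(x), by = q)]
    }))
  } else {
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    d <- g(target_srate, eeg$srate)
    out <- t(apply(eeg$data, 1, function(x)
      signal::resample(x, target_srate / d, eeg$srate / d)))
  }
  ev <- eeg$events
  if (nrow(ev)) {
    ev$sample <- pmax(1L, pmin(ncol(out), as.integer(
      round(ev$sample * target_srate / eeg$srate))))
  }
  continuous_eeg(out, target_srate, eeg$channel_labels, ev)
}

# even-order Hamming-sinc FIR length from the transition bandwidth, using
# the standard 3.3/(tb/fs) Hamming-window design heuristic
.fir_order <- function(tb_hz, srate) {
  n <- ceiling(3.3 / (tb_hz / srate))
  n + n %% 2
}

.zero_phase <- function(x, b) signal::filtfilt(signal::Ma(b), x)

#' Notch plus band-pass filtering (zero-phase Hamming-sinc FIR)
#'
#' The notch (band-stop around `notch` Hz, applied first) and the band-pass
#' are Hamming-windowed sinc FIR filters applied forward-backward
#' (zero-phase).  Transition bandwidth is 25% of the lower cutoff, at least
#' 2 Hz.
#' @param eeg a [continuous_eeg()].
#' @param low,high band-pass cutoffs, Hz (`high < srate/2`).
#' @param notch notch center frequency, Hz, or `NULL` to skip (also skipped
#'   when above Nyquist).
#' @param notch_halfwidth half-width of the stop band, Hz.
#' @return filtered [continuous_eeg()].
#' @export
filter_band <- function(eeg, low = 1, high = 20, notch = 50,
                        notch_halfwidth = 2) {
  nyq <- eeg$srate / 2
  if (low <= 0 || high <= low || high >= nyq)
    stop("invalid band: need 0 < low < high < srate/2", call. = FALSE)
  X <- eeg$data
  if (!is.null(notch) && notch + notch_halfwidth < nyq) {
    bn <- signal::fir1(.fir_order(1, eeg$srate),
                       c(notch - notch_halfwidth, notch + notch_halfwidth) /
                         nyq, type = "stop")
    X <- t(apply(X, 1, .zero_phase, b = bn))
  }
  tb <- max(low * 0.25, 2)
  bp <- signal::fir1(.fir_order(tb, eeg$srate), c(low, high) / nyq,
                     type = "pass")
  X <- t(apply(X, 1, .zero_phase, b = bp))
  continuous_eeg(X, eeg$srate, eeg$channel_labels, eeg$events)
}

#' Detect and interpolate artifact channels
#'
#' Channels are flagged when flat (near-zero variance) or when the robust
#' z-score of their log-variance (median/MAD over channels) exceeds
#' `z_threshold`.  Flagged channels are replaced by the inverse-distance
#' weighted average of the `k` nearest good channels (idealized spherical
#' montage positions).
#' @param eeg a [continuous_eeg()] with >= 4 channels.
#' @param z_threshold robust z-score threshold.
#' @param k number of neighbors used for interpolation.
#' @return list with `eeg` (repaired) and `bad_channels` (labels).
#' @export
detect_and_interpolate_bad_channels <- function(eeg, z_threshold = 5, k = 4) {
  stopifnot(nrow(eeg$data) >= 4)
  v <- apply(eeg$data, 1, stats::var)
  flat <- v < 1e-12
  lv <- log(pmax(v, 1e-12))
  med <- stats::median(lv[!flat])
  s <- stats::mad(lv[!flat])
  z <- if (s > 0) (lv - med) / s else rep(0, length(lv))
  bad <- which(flat | z > z_threshold)
  if (length(bad) > nrow(eeg$data) / 2)
    stop("recording unusable: more than half of the channels are bad",
         call. = FALSE)
  if (length(bad)) {
    pos <- as.matrix(standard_montage(eeg$channel_labels)[, c("x", "y", "z")])
    good <- setdiff(seq_len(nrow(eeg$data)), bad)
    for (b in bad) {
      d <- sqrt(colSums((t(pos[good, , drop = FALSE]) - pos[b, ])^2))
      nb <- good[order(d)][seq_len(min(k, length(good)))]
      w <- 1 / d[order(d)][seq_len(length(nb))]
      w <- w / sum(w)
      eeg$data[b, ] <- drop(w %*% eeg$data[nb, , drop = FALSE])
    }
  }
  list(eeg = eeg, bad_channels = eeg$channel_labels[bad])
}

#' Common-average re-referencing
#'
#' Subtracts the instantaneous mean over all channels from every channel;
#' idempotent.
#' @param eeg a [continuous_eeg()].
#' @return re-referenced [continuous_eeg()].
#' @export
rereference_car <- function(eeg) {
  eeg$data <- sweep(eeg$data, 2, colMeans(eeg$data))
  eeg
}

#' Extract epochs around events
#'
#' Epochs cover the half-open window `[window_s[1], window_s[2])` seconds
#' around each event (200 samples for the default [-0.2, 0.6) s at 250 Hz).
#' Events with labels in `exclude_labels` are dropped; events too close to
#' the recording edges are dropped with a warning.  Optional baseline
#' correction subtracts the per-trial per-channel mean over `baseline_s`.
#' @param eeg a [continuous_eeg()] with events labeled `error`/`correct`
#'   (other labels must be excluded via `exclude_labels`).
#' @param window_s epoch window, s, relative to each event.
#' @param baseline_s baseline window, s, or `NULL` for none.
#' @param exclude_labels event labels to drop.
#' @param subject_id stored in the result.
#' @return an [epochs_data()] (possibly with zero trials).
#' @export
extract_epochs <- function(eeg, window_s = c(-0.2, 0.6),
                           baseline_s = c(-0.2, 0),
                           exclude_labels = character(),
                           subject_id = "recorded") {
  ev <- eeg$events
  ev <- ev[!(ev$label %in% exclude_labels), , drop = FALSE]
  off <- seq(round(window_s[1] * eeg$srate),
             round(window_s[2] * eeg$srate) - 1)
  keep <- ev$sample + min(off) >= 1 & ev$sample + max(off) <= ncol(eeg$data)
  if (any(!keep))
    warning(sum(!keep), " event(s) too close to the recording edge; dropped")
  ev <- ev[keep, , drop = FALSE]
  times_ms <- off / eeg$srate * 1000
  n_tr <- nrow(ev)
  if (!n_tr) warning("no epochs extracted")
  data <- array(0, dim = c(n_tr, nrow(eeg$data), length(off)))
  for (i in seq_len(n_tr))
    data[i, , ] <- eeg$data[, ev$sample[i] + off]
  if (!is.null(baseline_s) && n_tr) {
    bl <- times_ms >= baseline_s[1] * 1000 & times_ms < baseline_s[2] * 1000
    base <- apply(data[, , bl, drop = FALSE], c(1, 2), mean)
    data <- data - as.vector(base)   # recycles over the samples dimension
  }
  .epochs_data(data, times_ms,
               factor(ev$label, levels = c("error", "correct")),
               eeg$srate, eeg$channel_labels, subject_id,
               provenance = list(source = "continuous"))
}
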