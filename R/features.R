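# ---------------------------------------------------------------------------
# Windowed-mean temporal features: the mean amplitude of selected channels in
# eight overlapping post-stimulus time slots.
# ---------------------------------------------------------------------------

#' Default feature windows (ms) and channels
#'
#' Eight overlapping slots [0,100), [100,200), [150,250), [200,300),
#' [250,350), [300,400), [350,450), [400,500) ms relative to the
#' time-locking event, evaluated at the eight-channel fronto-central montage
#' FC1, FC2, C3, Cz, C4, CP1, CP2, Pz.
#' @export
default_feature_windows <- function() {
  cbind(start = c(0, 100, 150, 200, 250, 300, 350, 400),
        end = c(100, 200, 250, 300, 350, 400, 450, 500))
}

#' @rdname default_feature_windows
#' @export
default_feature_channels <- function() .montage_sets$wet8

#' Windowed-mean feature extraction
#'
#' Feature (channel c, window w) is the arithmetic mean of channel c over the
#' samples whose time lies in the half-open interval [start, end) ms.
#' Feature order is channels outer, windows inner (`Cz[0,100)`, `Cz[100,200)`,
#' ..., next channel).
#' @param epochs an [epochs_data()].
#' @param channels channel labels (default: the eight-channel montage).
#' @param windows two-column matrix of [start, end) intervals in ms.
#' @return object of class `feature_matrix`: fields `values`
#'   (trials x features), `labels`, `window_defs`, `channels`, `normalizer`.
#' @export
window_mean_features <- function(epochs, channels = default_feature_channels(),
                                 windows = default_feature_windows()) {
  ch_idx <- match(channels, epochs$channel_labels)
  if (anyNA(ch_idx))
    stop("channel(s) not present: ",
         paste(channels[is.na(ch_idx)], collapse = ", "), call. = FALSE)
  t_ms <- epochs$times_ms
  n_tr <- dim(epochs$data)[1]
  nf <- length(ch_idx) * nrow(windows)
  vals <- matrix(0, n_tr, nf)
  nms <- character(nf)
  k <- 0
  for (ci in seq_along(ch_idx)) {
    for (wi in seq_len(nrow(windows))) {
      sel <- which(t_ms >= windows[wi, 1] & t_ms < windows[wi, 2])
      if (!length(sel))
        stop(sprintf("window [%g, %g) ms contains no samples",
                     windows[wi, 1], windows[wi, 2]), call. = FALSE)
      if (min(t_ms) > windows[wi, 1] || max(t_ms) < windows[wi, 2] - 1e-9)
        stop(sprintf("window [%g, %g) ms outside epoch time range",
                     windows[wi, 1], windows[wi, 2]), call. = FALSE)
      k <- k + 1
      vals[, k] <- rowMeans(epochs$data[, ch_idx[ci], sel, drop = FALSE])
      nms[k] <- sprintf("%s[%g,%g)", channels[ci], windows[wi, 1],
                        windows[wi, 2])
    }
  }
  colnames(vals) <- nms
  structure(list(values = vals, labels = epochs$labels,
                 window_defs = windows, channels = channels,
                 normalizer = NULL, subject_id = epochs$subject_id),
            class = "feature_matrix")
}

#' Fit / apply a per-feature z-score normalizer
#'
#' Statistics are estimated on the fitting set only and applied unchanged to
#' any other data (no leakage).  Features with zero standard deviation are
#' left unscaled (sd treated as 1) with a warning.
#' @param fm a `feature_matrix` (or plain matrix).
#' @return `fit_normalizer`: list with `mean` and `sd`.
#' @export
fit_normalizer <- function(fm) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else fm
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  zero <- !is.finite(sd) | sd <= 0
  if (any(zero)) {
    warning("constant feature(s) left unscaled: ",
            paste(which(zero), collapse = ", "))
    sd[zero] <- 1
  }
  list(mean = mu, sd = sd)
}

#' @rdname fit_normalizer
#' @param normalizer result of [fit_normalizer()].
#' @return `apply_normalizer`: the input with z-scored values and the
#'   normalizer recorded.
#' @export
apply_normalizer <- function(fm, normalizer) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else fm
  if (ncol(x) != length(normalizer$mean))
    stop("feature count mismatch between data and normalizer", call. = FALSE)
  z <- sweep(sweep(x, 2, normalizer$mean), 2, normalizer$sd, "/")
  if (inherits(fm, "feature_matrix")) {
    fm$values <- z
    fm$normalizer <- normalizer
    fm
  } else z
}

#' Export a feature matrix as TSV
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @export
write_features_tsv <- function(fm, path) {
  df <- data.frame(label = as.character(fm$labels), fm$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
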