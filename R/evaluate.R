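# ---------------------------------------------------------------------------
# Metrics, significance testing, ERP-level analysis and signal-quality
# diagnostics.  The error condition is the positive class everywhere.
# ---------------------------------------------------------------------------

#' Balanced accuracy and class rates
#'
#' TPR = fraction of error trials flagged as error; TNR = fraction of correct
#' trials flagged as correct; bACC = (TPR + TNR) / 2.
#' @param truth true labels (factor or character, both classes present).
#' @param pred predicted labels.
#' @return list with `tpr`, `tnr`, `bacc`.
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (!all(c("error", "correct") %in% truth))
    stop("true labels must contain both classes", call. = FALSE)
  tpr <- mean(pred[truth == "error"] == "error")
  tnr <- mean(pred[truth == "correct"] == "correct")
  list(tpr = tpr, tnr = tnr, bacc = (tpr + tnr) / 2)
}

#' Cross-validated permutation test
#'
#' The statistic (typically mean balanced accuracy of the full evaluation
#' pipeline, including any fold-internal downsampling/normalization) is
#' recomputed under `n_perm` random permutations of the labels; the p-value
#' uses the plus-one estimator `(#{permuted >= observed} + 1) / (n_perm + 1)`,
#' whose minimum attainable value is `1 / (n_perm + 1)`.
#'
#' @param stat_fn function taking a label vector and returning the scalar
#'   statistic.
#' @param labels the observed labels.
#' @param n_perm number of permutations (>= 20).
#' @return list with `p`, `observed`, `permuted` (vector of length
#'   `n_perm`).
#' @export
permutation_test <- function(stat_fn, labels, n_perm = 1000) {
  if (n_perm < 20) stop("n_perm must be at least 20", call. = FALSE)
  observed <- stat_fn(labels)
  permuted <- vapply(seq_len(n_perm),
                     function(i) stat_fn(sample(labels)), numeric(1))
  list(p = (sum(permuted >= observed) + 1) / (n_perm + 1),
       observed = observed, permuted = permuted)
}

# exact distribution of the signed-rank statistic over sign assignments of
# the doubled (integer) ranks: returns P(V >= v) and P(V <= v)
.signed_rank_exact_p <- function(ranks2, v2) {
  total <- sum(ranks2)
  dp <- numeric(total + 1)
  dp[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dp[seq_len(total + 1 - r)])
    dp <- dp + shifted
  }
  dp <- dp / 2^length(ranks2)
  ge <- sum(dp[(v2 + 1):(total + 1)])
  le <- sum(dp[1:(v2 + 1)])
  c(ge = ge, le = le)
}

#' Paired Wilcoxon signed-rank comparison
#'
#' Zero differences are dropped; ties receive midranks.  For n <= 25 retained
#' pairs the p-value is exact (full enumeration of the 2^n sign assignments
#' via the rank-sum distribution); beyond that a normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param a,b equal-length paired metric vectors (n >= 5).
#' @param alternative `"two.sided"`, `"greater"` (A > B) or `"less"`.
#' @return list with `p`, `statistic` (V, rank sum of positive differences),
#'   `n_effective`, `method`.
#' @export
compare_paired <- function(a, b, alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) == length(b), length(a) >= 5)
  d <- a - b
  d <- d[d != 0]
  if (!length(d))
    stop("all paired differences are zero; comparison is degenerate",
         call. = FALSE)
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25) {
    ranks2 <- as.integer(round(2 * r))
    v2 <- as.integer(round(2 * v))
    p2 <- .signed_rank_exact_p(ranks2, v2)
    p <- switch(alternative,
                greater = p2[["ge"]],
                less = p2[["le"]],
                two.sided = min(1, 2 * min(p2)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z_ge <- (v - mu - 0.5) / sqrt(sig2)
    z_le <- (v - mu + 0.5) / sqrt(sig2)
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p_le <- stats::pnorm(z_le)
    p <- switch(alternative, greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "normal approximation"
  }
  list(p = unname(p), statistic = v, n_effective = n, method = method)
}

# Welch two-sample t-test p-values per column of two matrices
.welch_p <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(t), df)
}

#' Pointwise FDR-corrected class difference mask
#'
#' Per timepoint, single-trial amplitudes of the two conditions are compared
#' with a Welch two-sample t-test; Benjamini-Hochberg correction over
#' timepoints controls the false discovery rate at `alpha`.
#' @param epochs an [epochs_data()] containing both conditions.
#' @param channel channel label.
#' @param alpha FDR level (0 gives an empty mask).
#' @return logical vector over timepoints (`TRUE` = significant), with the
#'   adjusted p-values as attribute `"p_adj"`.
#' @export
pointwise_fdr_mask <- function(epochs, channel = "Cz", alpha = 0.05) {
  X <- channel_matrix(epochs, channel)
  A <- X[epochs$labels == "error", , drop = FALSE]
  B <- X[epochs$labels == "correct", , drop = FALSE]
  if (nrow(A) < 2 || nrow(B) < 2)
    stop("need at least 2 trials per class", call. = FALSE)
  p <- .welch_p(A, B)
  p_adj <- stats::p.adjust(p, method = "BH")
  structure(p_adj <= alpha & alpha > 0, p_adj = p_adj)
}

#' Grand-average ERPs and difference wave
#'
#' Class averages are computed per subject, then averaged (unweighted) across
#' subjects; the difference wave is error minus correct.  Optional per-trial
#' baseline correction subtracts the mean over the baseline window.
#' @param subjects list of [epochs_data()] with a common time axis (a single
#'   object is promoted to a list).
#' @param channel channel label.
#' @param baseline_ms length-2 window (e.g. `c(-200, 0)`) or `NULL` for no
#'   baseline correction.
#' @return list of class `erp_summary`: `times_ms`, `error`, `correct`,
#'   `difference`, per-subject matrices `error_by_subject`,
#'   `correct_by_subject`, `n_subjects`.
#' @export
grand_average <- function(subjects, channel = "Cz", baseline_ms = c(-200, 0)) {
  if (inherits(subjects, "epochs_data")) subjects <- list(subjects)
  times <- subjects[[1]]$times_ms
  for (s in subjects)
    if (!isTRUE(all.equal(s$times_ms, times)))
      stop("subjects have mismatched time axes", call. = FALSE)
  per_class <- function(s, cls) {
    X <- channel_matrix(s, channel)[s$labels == cls, , drop = FALSE]
    if (!is.null(baseline_ms)) {
      bl <- times >= baseline_ms[1] & times < baseline_ms[2]
      X <- X - rowMeans(X[, bl, drop = FALSE])
    }
    colMeans(X)
  }
  err <- t(vapply(subjects, per_class, numeric(length(times)), cls = "error"))
  cor <- t(vapply(subjects, per_class, numeric(length(times)),
                  cls = "correct"))
  structure(list(times_ms = times, error = colMeans(err),
                 correct = colMeans(cor),
                 difference = colMeans(err) - colMeans(cor),
                 error_by_subject = err, correct_by_subject = cor,
                 n_subjects = length(subjects)), class = "erp_summary")
}

#' Default peak-search intervals
#'
#' Positive peaks in [50, 250] and [200, 400] ms, negative peaks in
#' [200, 400] and [400, 600] ms.
#' @export
default_peak_intervals <- function() {
  data.frame(start_ms = c(50, 200, 200, 400), end_ms = c(250, 400, 400, 600),
             polarity = c("positive", "positive", "negative", "negative"))
}

#' Most prominent peaks of a difference wave
#'
#' Per interval, the sample maximizing signed amplitude (maximum for positive
#' polarity, minimum for negative); a monotone segment therefore returns an
#' interval endpoint.
#' @param times_ms time axis.
#' @param wave amplitude vector (same length).
#' @param intervals data.frame with `start_ms`, `end_ms`, `polarity`.
#' @return data.frame: interval columns plus `latency_ms`, `amplitude`.
#' @export
find_peaks <- function(times_ms, wave, intervals = default_peak_intervals()) {
  out <- intervals
  out$latency_ms <- NA_real_; out$amplitude <- NA_real_
  for (i in seq_len(nrow(intervals))) {
    sel <- which(times_ms >= intervals$start_ms[i] &
                   times_ms <= intervals$end_ms[i])
    if (!length(sel))
      stop(sprintf("interval [%g, %g] ms outside the time axis",
                   intervals$start_ms[i], intervals$end_ms[i]), call. = FALSE)
    j <- if (intervals$polarity[i] == "positive") sel[which.max(wave[sel])]
         else sel[which.min(wave[sel])]
    out$latency_ms[i] <- times_ms[j]
    out$amplitude[i] <- wave[j]
  }
  out
}

#' Permuted baseline-RMS noise distribution
#'
#' Single-trial noise estimate: per permutation, `n_trials_per_perm` correct
#' epochs are sampled per subject, the root mean square over the pre-onset
#' baseline window is computed per trial per channel and averaged over
#' electrodes, then trials, then subjects, in this order.  Returns the mean
#' and standard deviation of the permuted distribution.
#' @param subjects list of [epochs_data()] (single object promoted).
#' @param n_perm number of permutations.
#' @param n_trials_per_perm correct epochs sampled per permutation (sampled
#'   with replacement, with a message, if fewer are available).
#' @param baseline_ms baseline window, default the 200 ms before onset.
#' @return list with `mean_rms`, `std_rms`, `values`.
#' @export
baseline_rms_distribution <- function(subjects, n_perm = 10000,
                                      n_trials_per_perm = 575,
                                      baseline_ms = c(-200, 0)) {
  if (inherits(subjects, "epochs_data")) subjects <- list(subjects)
  per_trial <- lapply(subjects, function(s) {
    bl <- s$times_ms >= baseline_ms[1] & s$times_ms < baseline_ms[2]
    if (!any(bl)) stop("no pre-onset baseline samples", call. = FALSE)
    X <- s$data[s$labels == "correct", , bl, drop = FALSE]
    rms_tc <- sqrt(apply(X^2, c(1, 2), mean))   # trials x channels
    rowMeans(rms_tc)                            # average over electrodes
  })
  short <- vapply(per_trial, length, 0L) < n_trials_per_perm
  if (any(short))
    message("fewer correct epochs than requested; sampling with replacement")
  values <- vapply(seq_len(n_perm), function(i) {
    mean(vapply(per_trial, function(a)
      mean(a[sample.int(length(a), n_trials_per_perm, replace = TRUE)]),
      numeric(1)))
  }, numeric(1))
  list(mean_rms = mean(values), std_rms = stats::sd(values), values = values)
}

#' Averaged single-trial amplitude spectra
#'
#' FFT amplitude spectra of randomly selected correct epochs at one channel,
#' averaged across trials.
#' @param epochs an [epochs_data()].
#' @param channel channel label.
#' @param n_trials number of correct trials to sample (with replacement,
#'   with a message, if fewer are available).
#' @return list with `freq_hz` and `amplitude` (length `n_samples/2 + 1`).
#' @export
single_trial_spectra <- function(epochs, channel = "Cz", n_trials = 575) {
  X <- channel_matrix(epochs, channel)[epochs$labels == "correct", ,
                                       drop = FALSE]
  replace <- nrow(X) < n_trials
  if (replace)
    message("fewer correct epochs than requested; sampling with replacement")
  idx <- sample.int(nrow(X), n_trials, replace = replace)
  n <- ncol(X)
  nf <- floor(n / 2) + 1
  amp <- rowMeans(vapply(idx, function(i) {
    a <- Mod(stats::fft(X[i, ])) / n
    a <- a[1:nf]
    a[2:(nf - 1)] <- 2 * a[2:(nf - 1)]
    a
  }, numeric(nf)))
  list(freq_hz = (0:(nf - 1)) * epochs$srate / n, amplitude = amp)
}

#' ERP image of single error trials
#'
#' The average over all correct trials is subtracted from each error trial at
#' the given channel; traces are kept in original trial order (first trial =
#' first row = bottom of the conventional plot) and smoothed with a moving
#' average over `smooth` consecutive trials, the window truncated at the
#' edges.  The across-trial mean ERP is attached.
#' @param epochs an [epochs_data()].
#' @param channel channel label.
#' @param smooth moving-average length in trials (1 = no smoothing).
#' @return list with `image` (error trials x time) and `mean_erp`.
#' @export
erp_image <- function(epochs, channel = "Cz", smooth = 5) {
  X <- channel_matrix(epochs, channel)
  E <- X[epochs$labels == "error", , drop = FALSE]
  if (!nrow(E)) stop("no error trials", call. = FALSE)
  avg_correct <- colMeans(X[epochs$labels == "correct", , drop = FALSE])
  D <- sweep(E, 2, avg_correct)
  half <- (smooth - 1) / 2
  S <- D
  if (smooth > 1) {
    for (i in seq_len(nrow(D))) {
      lo <- max(1, ceiling(i - half)); hi <- min(nrow(D), floor(i + half))
      S[i, ] <- colMeans(D[lo:hi, , drop = FALSE])
    }
  }
  list(image = S, mean_erp = colMeans(D))
}
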