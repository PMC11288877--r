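# brute-force signed-rank null: enumerate all 2^n sign assignments
oracle_signed_rank_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  ge <- mean(v_all >= v_obs - 1e-9)
  le <- mean(v_all <= v_obs + 1e-9)
  switch(alternative, greater = ge, less = le,
         two.sided = min(1, 2 * min(ge, le)))
}

test_that("balanced accuracy is the mean of the class rates", {
  truth <- rep(c("error", "correct"), c(10, 40))
  pred <- truth
  expect_equal(balanced_accuracy(truth, pred),
               list(tpr = 1, tnr = 1, bacc = 1))
  # all-correct predictor at 20% error rate
  expect_equal(balanced_accuracy(truth, rep("correct", 50)),
               list(tpr = 0, tnr = 1, bacc = 0.5))
  # TPR 0.7, TNR 0.9 -> bACC 0.8
  pred2 <- truth
  pred2[1:3] <- "correct"          # 7/10 errors kept
  pred2[11:14] <- "error"          # 36/40 correct kept
  m <- balanced_accuracy(truth, pred2)
  expect_equal(m$bacc, (0.7 + 0.9) / 2)
  expect_error(balanced_accuracy(rep("error", 5), rep("error", 5)),
               "both classes")
})

test_that("permutation p-values use the plus-one estimator and calibrate
           under the null", {
  labels <- factor(rep(c("error", "correct"), c(20, 80)),
                   levels = c("error", "correct"))
  # a statistic maximal for the observed labels attains the minimum p
  set.seed(51)
  res <- permutation_test(function(l) mean(l == labels), labels,
                          n_perm = 1000)
  expect_equal(res$p, 1 / 1001)
  # a label-independent constant statistic gives p ~= 1
  set.seed(52)
  res2 <- permutation_test(function(l) 0.5, labels, n_perm = 100)
  expect_equal(res2$p, 1)
  expect_error(permutation_test(function(l) 0, labels, n_perm = 10),
               "n_perm")
  # under a null (continuous) statistic the p-values are uniform on the
  # permutation grid
  set.seed(53)
  m <- 39
  ps <- replicate(60, {
    x <- stats::rnorm(length(labels))
    permutation_test(function(l) mean(x[l == "error"]), labels,
                     n_perm = m)$p
  })
  ks <- suppressWarnings(
    stats::ks.test(ps, function(q) pmin(1, floor(q * (m + 1)) / (m + 1))))
  expect_gt(ks$p.value, 0.01)
})

test_that("signed-rank comparison matches exact enumeration and the stock
           implementation", {
  # constant positive offset, n = 10: one-sided p is exactly 1/1024
  a <- stats::rnorm(10); b <- a - 1
  expect_equal(compare_paired(a, b, "greater")$p, 1 / 1024)
  # degenerate all-zero differences are refused
  expect_error(compare_paired(a, a), "degenerate")
  # enumeration oracle on random data, with and without ties
  set.seed(54)
  for (i in 1:8) {
    n <- sample(6:10, 1)
    x <- stats::rnorm(n)
    y <- x - stats::rnorm(n)
    if (i > 4) y[1:2] <- x[1:2] - abs(y[3] - x[3])   # induce tied |diffs|
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(compare_paired(x, y, alt)$p,
                   oracle_signed_rank_p(x - y, alt), tolerance = 1e-12)
    }
  }
  # tie-free data also agrees with stats::wilcox.test's exact p
  set.seed(55)
  x <- stats::rnorm(12); y <- stats::rnorm(12)
  expect_equal(compare_paired(x, y, "two.sided")$p,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("pointwise FDR mask flags injected differences and respects the
           null", {
  n_s <- 100
  times <- seq(-200, by = 4, length.out = n_s)
  mk <- function(offset_window = NULL) {
    data <- array(stats::rnorm(60 * 1 * n_s), dim = c(60, 1, n_s))
    if (!is.null(offset_window)) {
      sel <- times >= offset_window[1] & times < offset_window[2]
      data[1:20, 1, sel] <- data[1:20, 1, sel] + 5
    }
    epochs_data(data, times, rep(c("error", "correct"), c(20, 40)), 250,
                "Cz")
  }
  set.seed(56)
  ep <- mk(c(200, 300))
  mask <- pointwise_fdr_mask(ep, "Cz", 0.05)
  expect_true(all(mask[times >= 204 & times < 296]))
  expect_identical(sum(pointwise_fdr_mask(ep, "Cz", 0)), 0L)
  # null calibration: average flagged fraction stays at or below alpha
  set.seed(57)
  frac <- replicate(100, mean(pointwise_fdr_mask(mk(), "Cz", 0.05)))
  expect_lte(mean(frac), 0.05)
})

test_that("grand averages and difference waves obey their identities", {
  n_s <- 50
  times <- seq(-200, by = 4, length.out = n_s)
  tr_err <- sin(seq_len(n_s) / 5); tr_cor <- cos(seq_len(n_s) / 7)
  data <- array(0, dim = c(2, 1, n_s))
  data[1, 1, ] <- tr_err; data[2, 1, ] <- tr_cor
  ep <- epochs_data(data, times, c("error", "correct"), 250, "Cz")
  ga <- grand_average(ep, "Cz", baseline_ms = NULL)
  expect_equal(ga$difference, tr_err - tr_cor)
  # zero correct class: difference equals the error average
  data[2, 1, ] <- 0
  ep2 <- epochs_data(data, times, c("error", "correct"), 250, "Cz")
  ga2 <- grand_average(ep2, "Cz", baseline_ms = NULL)
  expect_equal(ga2$difference, ga2$error)
  # subject order does not matter
  s1 <- ep; s2 <- ep2
  g12 <- grand_average(list(s1, s2), "Cz", baseline_ms = NULL)
  g21 <- grand_average(list(s2, s1), "Cz", baseline_ms = NULL)
  expect_equal(g12$difference, g21$difference)
  # mismatched time axes are refused
  s3 <- epochs_data(data, times + 4, c("error", "correct"), 250, "Cz")
  expect_error(grand_average(list(s1, s3)), "time axes")
})

test_that("peak picking returns the extremum of the requested polarity", {
  times <- seq(0, 600, by = 4)
  wave <- 10 * exp(-((times - 320)^2) / (2 * 30^2))
  pk <- find_peaks(times, wave,
                   data.frame(start_ms = 200, end_ms = 400,
                              polarity = "positive"))
  expect_equal(pk$latency_ms, 320)
  expect_equal(pk$amplitude, 10)
  # monotone ramp: endpoint is returned
  ramp <- times / 100
  pk2 <- find_peaks(times, ramp,
                    data.frame(start_ms = 100, end_ms = 300,
                               polarity = "positive"))
  expect_equal(pk2$latency_ms, 300)
  # negative-polarity search on a positive bump: least-positive sample
  pk3 <- find_peaks(times, wave,
                    data.frame(start_ms = 200, end_ms = 400,
                               polarity = "negative"))
  expect_equal(pk3$amplitude, min(wave[times >= 200 & times <= 400]))
  expect_error(find_peaks(times, wave,
                          data.frame(start_ms = 900, end_ms = 950,
                                     polarity = "positive")), "outside")
})

test_that("baseline RMS distribution matches closed-form cases", {
  n_s <- 100
  times <- seq(-200, by = 4, length.out = n_s)
  mk <- function(fill) {
    data <- array(fill, dim = c(30, 2, n_s))
    epochs_data(data, times, rep("correct", 30), 250, c("Cz", "Pz"),
                provenance = list())
  }
  # zero data and constant data (need an error trial too? only correct used)
  z <- suppressMessages(baseline_rms_distribution(mk(0), n_perm = 50,
                                                  n_trials_per_perm = 10))
  expect_equal(z$mean_rms, 0)
  c5 <- suppressMessages(baseline_rms_distribution(mk(-5), n_perm = 50,
                                                   n_trials_per_perm = 10))
  expect_equal(c5$mean_rms, 5)
  # white noise of sd sigma: RMS converges to sigma
  set.seed(58)
  data <- array(stats::rnorm(200 * 2 * n_s, sd = 3), dim = c(200, 2, n_s))
  ep <- epochs_data(data, times, rep("correct", 200), 250, c("Cz", "Pz"))
  w <- baseline_rms_distribution(ep, n_perm = 200, n_trials_per_perm = 150)
  expect_lt(abs(w$mean_rms - 3), 0.1)
})

test_that("single-trial spectra localize tones and brown noise", {
  n_s <- 250
  times <- seq(-500, by = 4, length.out = n_s)
  t_s <- times / 1000
  tone <- sin(2 * pi * 10 * t_s)
  data <- array(rep(tone, each = 30), dim = c(30, 1, n_s))
  ep <- epochs_data(data, times, rep("correct", 30), 250, "Cz")
  set.seed(59)
  sp <- suppressMessages(single_trial_spectra(ep, "Cz", n_trials = 40))
  expect_equal(sp$freq_hz[which.max(sp$amplitude)], 10)
  expect_length(sp$amplitude, n_s / 2 + 1)
  # brown-noise epochs keep their 1/f^2 power decay in the mean spectrum
  set.seed(60)
  datb <- array(0, dim = c(50, 1, n_s))
  for (i in 1:50) datb[i, 1, ] <- brown_noise(n_s)
  epb <- epochs_data(datb, times, rep("correct", 50), 250, "Cz")
  spb <- single_trial_spectra(epb, "Cz", n_trials = 50)
  sel <- spb$freq_hz >= 1 & spb$freq_hz <= 40
  fit <- stats::lm(log10(spb$amplitude[sel]^2) ~ log10(spb$freq_hz[sel]))
  expect_lt(abs(unname(stats::coef(fit)[2]) + 2), 0.5)
})

test_that("ERP images smooth over consecutive trials with truncated edges", {
  n_s <- 20
  times <- seq(0, by = 4, length.out = n_s)
  # alternating +1/-1 error trials, zero correct average
  data <- array(0, dim = c(12, 1, n_s))
  for (i in 1:10) data[i, 1, ] <- (-1)^(i + 1)
  labels <- c(rep("error", 10), "correct", "correct")
  ep <- epochs_data(data, times, labels, 250, "Cz")
  img <- erp_image(ep, "Cz", smooth = 5)
  # interior rows: mean of 5 alternating +-1 values = +-0.2
  expect_equal(img$image[5, 1], 0.2)
  expect_equal(img$image[6, 1], -0.2)
  # smoothing of 1 returns raw difference traces
  raw <- erp_image(ep, "Cz", smooth = 1)
  expect_equal(raw$image[3, ], rep(1, n_s))
  # identical trials stay identical after smoothing
  data2 <- data; for (i in 1:10) data2[i, 1, ] <- 7
  ep2 <- epochs_data(data2, times, labels, 250, "Cz")
  img2 <- erp_image(ep2, "Cz", smooth = 5)
  expect_true(all(img2$image == 7))
})
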