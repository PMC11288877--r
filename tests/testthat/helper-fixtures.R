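# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small spherical lead field shared by most tests (deterministic)
test_leadfield <- function() {
  memo("lf_small",
       build_spherical_leadfield("biosemi64", n_sources = 2000, seed = 7))
}

# a fast simulated subject with both conditions
test_subject <- function() {
  memo("subj_small", {
    cfg <- sim_config(n_epochs = 600, n_lf_sources = 2000)
    simulate_subject(cfg, test_leadfield(), subject_seed = 21)
  })
}

# least-squares log-log slope of the periodogram over a frequency band
psd_slope <- function(x, srate, band = c(1, 40)) {
  n <- length(x)
  spec <- Mod(stats::fft(x))^2 / n
  f <- (0:(n - 1)) * srate / n
  sel <- f >= band[1] & f <= band[2] & seq_along(f) <= n / 2
  fit <- stats::lm(log10(spec[sel]) ~ log10(f[sel]))
  unname(stats::coef(fit)[2])
}

# feature matrix with gaussian class separation, for classifier tests
toy_features <- function(n_error = 40, n_correct = 160, n_feat = 6,
                         delta = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- factor(rep(c("error", "correct"), c(n_error, n_correct)),
                levels = c("error", "correct"))
  x <- matrix(stats::rnorm((n_error + n_correct) * n_feat),
              n_error + n_correct, n_feat)
  x[lab == "error", ] <- x[lab == "error", ] + delta
  structure(list(values = x, labels = lab, window_defs = NULL,
                 channels = NULL, normalizer = NULL, subject_id = "toy"),
            class = "feature_matrix")
}
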