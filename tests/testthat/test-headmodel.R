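# Independent reference for the per-order radial transfer coefficients:
# straightforward (unscaled) translation of the boundary-value problem,
# solved on the raw matrix.  Accurate for moderate orders, where the raw
# system is still well-conditioned.
oracle_shell_h <- function(n_max, geom = spherical_head_geometry()) {
  r <- geom$radii_mm / geom$radii_mm[3]
  s <- geom$sigma
  r1 <- r[1]; r2 <- r[2]
  h <- numeric(n_max)
  for (n in seq_len(n_max)) {
    M <- rbind(
      c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0),
      c(s[1] * n * r1^(n - 1), -s[2] * n * r1^(n - 1),
        s[2] * (n + 1) * r1^(-(n + 2)), 0, 0),
      c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1))),
      c(0, s[2] * n * r2^(n - 1), -s[2] * (n + 1) * r2^(-(n + 2)),
        -s[3] * n * r2^(n - 1), s[3] * (n + 1) * r2^(-(n + 2))),
      c(0, 0, 0, n, -(n + 1)))
    rhs <- c(-r1^(-(n + 1)), s[1] * (n + 1) * r1^(-(n + 2)), 0, 0, 0)
    x <- solve(M, rhs)
    h[n] <- (x[4] + x[5]) * r1^(n + 1)
  }
  h
}

test_that("shell coefficients match the homogeneous closed form and an
           independent unscaled solve", {
  # equal conductivities: h_n has the classic closed form (2n+1)/n * r1^(n+1)
  geom <- spherical_head_geometry()
  geom$sigma[] <- 1
  n <- 1:30
  h <- errpsim:::.shell_coefficients(30, geom)
  expect_equal(h, (2 * n + 1) / n * (80 / 92)^(n + 1), tolerance = 1e-12)
  # default three-shell geometry vs the independent raw-matrix solve
  h3 <- errpsim:::.shell_coefficients(40)
  expect_equal(h3, oracle_shell_h(40), tolerance = 1e-8)
})

test_that("truncated series agrees with high-order evaluation within 1%", {
  mont <- standard_montage("biosemi64")
  elec <- as.matrix(mont[, c("x", "y", "z")])
  set.seed(31)
  for (i in 1:20) {
    d <- stats::rnorm(3)
    d <- d / sqrt(sum(d^2)) * stats::runif(1, 5, 75)
    G60 <- errpsim:::.dipole_gain(d, elec, 60)
    G200 <- errpsim:::.dipole_gain(d, elec, 200)
    expect_lt(max(abs(G60 - G200)) / max(abs(G200)), 0.01)
  }
})

test_that("a radial dipole beneath Cz projects maximally to Cz", {
  mont <- standard_montage("biosemi64")
  elec <- as.matrix(mont[, c("x", "y", "z")])
  g <- errpsim:::.dipole_gain(c(0, 0, 60), elec)[, 3]
  expect_identical(mont$label[which.max(abs(g))], "Cz")
})

test_that("forward projection is linear and superposition-exact", {
  lf <- test_leadfield()
  m1 <- c(0.3, -1.2, 0.5); m2 <- c(-0.7, 0.1, 2)
  p1 <- project_source(lf, 17, m1)
  p2 <- project_source(lf, 17, m2)
  expect_equal(project_source(lf, 17, 2.5 * m1 - 3 * m2),
               2.5 * p1 - 3 * p2, tolerance = 1e-12)
  # doubling the moment doubles every channel gain
  expect_equal(project_source(lf, 17, 2 * m1), 2 * p1, tolerance = 1e-12)
})

test_that("lead field construction is deterministic for a fixed seed", {
  a <- build_spherical_leadfield(n_sources = 150, seed = 5)
  b <- build_spherical_leadfield(n_sources = 150, seed = 5)
  expect_identical(a$gains, b$gains)
  expect_identical(a$source_pos_mm, b$source_pos_mm)
})

test_that("lead field persistence round-trips and validates", {
  lf <- build_spherical_leadfield(n_sources = 150, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  write_leadfield(lf, path)
  lf2 <- load_leadfield(path)
  expect_equal(lf2$gains, lf$gains)
  expect_equal(lf2$channel_labels, lf$channel_labels)
  # shape passthrough
  expect_identical(dim(lf2$gains), c(64L, 150L, 3L))
  # corrupted gains are rejected with a labeled error
  bad <- unclass(lf)
  bad$gains[1, 1, 1] <- NaN
  saveRDS(bad, path)
  expect_error(load_leadfield(path), "non-finite gains")
  bad$gains <- NULL
  saveRDS(bad, path)
  expect_error(load_leadfield(path), "missing field")
})

test_that("pick_source_near honors radius and is uniform over candidates", {
  lf <- test_leadfield()
  center <- c(0, 12, 62)
  # radius 0: the single nearest source
  d <- sqrt(colSums((t(lf$source_pos_mm) - center)^2))
  expect_identical(pick_source_near(lf, center, 0)$source_index,
                   which.min(d))
  # radius 10 mm: always inside
  set.seed(41)
  for (i in 1:50) {
    sel <- pick_source_near(lf, center, 10)
    expect_lte(sqrt(sum((lf$source_pos_mm[sel$source_index, ] - center)^2)),
               10)
  }
  # empirical distribution over qualifying sources is uniform
  cand <- which(d <= 10)
  set.seed(42)
  draws <- replicate(4000, pick_source_near(lf, center, 10)$source_index)
  counts <- table(factor(draws, levels = cand))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  # empty candidate set: labeled error with the nearest distance
  expect_error(pick_source_near(lf, c(0, 0, 200), 5), "nearest available")
})

test_that("pick_spaced_sources enforces the pairwise minimum distance", {
  lf <- test_leadfield()
  set.seed(43)
  idx <- pick_spaced_sources(lf, 40, 25)
  expect_length(idx, 40)
  D <- as.matrix(stats::dist(lf$source_pos_mm[idx, ]))
  expect_true(all(D[upper.tri(D)] >= 25))
  # n = 1: no spacing constraint applies
  expect_length(pick_spaced_sources(lf, 1, 1e6), 1)
  # spacing beyond the head diameter is infeasible and reports the count
  expect_error(pick_spaced_sources(lf, 2, 500, max_restarts = 3),
               "best achieved: 1")
})

test_that("orientation deviation preserves unit norm within the analytic
           angle bound", {
  v <- c(1, 1, 1) / sqrt(3)
  expect_identical(orient_with_deviation(v, 0), v)
  # worst case over the +-20% component-scaling box is attained at a corner
  corners <- as.matrix(expand.grid(c(0.8, 1.2), c(0.8, 1.2), c(0.8, 1.2)))
  max_angle <- max(apply(corners, 1, function(s) {
    w <- v * s
    acos(pmin(1, sum(v * w) / sqrt(sum(w^2))))
  }))
  set.seed(44)
  for (i in 1:500) {
    w <- orient_with_deviation(v, 0.2)
    expect_equal(sum(w^2), 1, tolerance = 1e-12)
    expect_lte(acos(pmin(1, sum(v * w))), max_angle + 1e-9)
  }
  set.seed(45); a <- orient_with_deviation(v, 0.2)
  set.seed(45); b <- orient_with_deviation(v, 0.2)
  expect_identical(a, b)
})

test_that("montage geometry is plausible and validated", {
  mont <- standard_montage("biosemi64")
  expect_identical(nrow(mont), 64L)
  expect_false(anyDuplicated(mont$label) > 0)
  expect_equal(unlist(mont[mont$label == "Cz", c("x", "y", "z")]),
               c(x = 0, y = 0, z = 92), tolerance = 1e-12)
  r <- sqrt(mont$x^2 + mont$y^2 + mont$z^2)
  expect_equal(r, rep(92, 64), tolerance = 1e-9)
  expect_error(standard_montage(c("Cz", "XX9")), "unknown channel label")
  # the eight-channel montage is a subset with identical coordinates
  w8 <- standard_montage("wet8")
  m <- merge(w8, mont, by = "label")
  expect_equal(m$x.x, m$x.y)
})
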