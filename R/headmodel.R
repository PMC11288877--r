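# ---------------------------------------------------------------------------
# Three-shell concentric-sphere forward model
#
# The scalp potential of a current dipole inside a set of concentric
# conducting shells expands in Legendre harmonics.  Per harmonic order n the
# potential in each shell is A r^n + B r^-(n+1); the dipole adds the known
# free-medium expansion in the innermost region.  Matching potential and
# radial current at the two interfaces plus the insulating outer boundary
# gives a small linear system per order.  Unknowns are rescaled so every
# matrix entry is a ratio of radii <= 1 times O(n), which keeps the solve
# well-conditioned to high order.
# ---------------------------------------------------------------------------

#' Shell geometry and conductivities of the default spherical head
#'
#' Radii 80/85/92 mm (brain, skull, scalp) with conductivity ratio
#' 1 : 1/80 : 1.
#' @return list with `radii_mm` and `sigma`.
#' @export
spherical_head_geometry <- function() {
  list(radii_mm = c(brain = 80, skull = 85, scalp = 92),
       sigma = c(brain = 1, skull = 1 / 80, scalp = 1))
}

# Per-order radial transfer coefficients h_n for a dipole in the brain shell.
# Returns h[n], n = 1..n_max, defined such that the scalp-surface potential is
#   V = 1/(4*pi*sigma1*r1^2) * sum_n (b/r1)^(n-1) * h_n *
#       [ n*q_r*P_n(cos g) + P_n'(cos g) * (u.e_hat - (u.p_hat) cos g) ]
# with b the (normalized) source depth, g the source-electrode angle.
.shell_coefficients <- function(n_max, geom = spherical_head_geometry()) {
  r <- geom$radii_mm / geom$radii_mm[3]   # normalize scalp radius to 1
  s <- geom$sigma
  r1 <- r[1]; r2 <- r[2]
  h <- numeric(n_max)
  for (n in seq_len(n_max)) {
    q12 <- (r1 / r2)^n
    q12p <- (r1 / r2)^(n + 1)
    r2n <- r2^n
    r2p <- r2^(n + 1)
    # unknowns: A1', A2', B2', A3', B3' (rescaled; see file header)
    M <- rbind(
      c(1, -q12, -1, 0, 0),
      c(s[1] * n, -s[2] * n * q12, s[2] * (n + 1), 0, 0),
      c(0, 1, q12p, -r2n, -1),
      c(0, s[2] * n, -s[2] * (n + 1) * q12p, -s[3] * n * r2n, s[3] * (n + 1)),
      c(0, 0, 0, n, -(n + 1) * r2p))
    rhs <- c(-1, s[1] * (n + 1), 0, 0, 0)
    x <- solve(M, rhs)
    h[n] <- x[4] + x[5] * r2p
  }
  h
}

# Legendre polynomials P_n(x) and derivatives P_n'(x) for n = 1..n_max,
# vectorized over x; derivative via P'_{n+1} = P'_{n-1} + (2n+1) P_n
# (stable at x = +-1).
.legendre_table <- function(x, n_max) {
  m <- length(x)
  P <- matrix(0, m, n_max)
  dP <- matrix(0, m, n_max)
  Pm1 <- rep(1, m)        # P_0
  P[, 1] <- x             # P_1
  dPm1 <- rep(0, m)       # P_0'
  dP[, 1] <- 1            # P_1'
  for (n in 1:(n_max - 1)) {
    P[, n + 1] <- ((2 * n + 1) * x * P[, n] - n * Pm1) / (n + 1)
    dP[, n + 1] <- dPm1 + (2 * n + 1) * P[, n]
    Pm1 <- P[, n]
    dPm1 <- dP[, n]
  }
  list(P = P, dP = dP)
}

# Scalp potentials (one value per electrode row of `elec_mm`) for unit dipoles
# along x, y, z at `src_mm`.  Returns an n_elec x 3 matrix.
.dipole_gain <- function(src_mm, elec_mm, n_terms = 60,
                         geom = spherical_head_geometry(), h = NULL) {
  r3 <- geom$radii_mm[3]
  b <- sqrt(sum(src_mm^2)) / r3
  r1 <- geom$radii_mm[1] / r3
  e_hat <- elec_mm / r3   # electrodes assumed on the scalp sphere (|.| = 1)
  if (is.null(h)) h <- .shell_coefficients(n_terms, geom)
  n_seq <- seq_len(n_terms)
  depth <- (b / r1)^(n_seq - 1)
  if (b < 1e-12) {
    p_hat <- c(0, 0, 1)   # dipole at the center: orientation axis arbitrary
    depth <- c(1, rep(0, n_terms - 1))
  } else {
    p_hat <- src_mm / sqrt(sum(src_mm^2))
  }
  cosg <- pmax(-1, pmin(1, drop(e_hat %*% p_hat)))
  leg <- .legendre_table(cosg, n_terms)
  scale <- 1 / (4 * pi * geom$sigma[1] * r1^2 * r3^2)  # 1/mm^2 units
  w <- h * depth
  # radial part: sum_n w_n * n * P_n ; tangential: sum_n w_n * P_n'
  rad <- leg$P %*% (w * n_seq)
  tan <- leg$dP %*% w
  G <- matrix(0, nrow(elec_mm), 3)
  for (k in 1:3) {
    u <- c(0, 0, 0); u[k] <- 1
    qr <- sum(u * p_hat)
    ue <- drop(e_hat %*% u)
    G[, k] <- scale * (qr * rad + tan * (ue - qr * cosg))
  }
  G
}

# ---------------------------------------------------------------------------
# LeadField container
# ---------------------------------------------------------------------------

.validate_leadfield <- function(lf) {
  stopifnot(is.list(lf))
  need <- c("gains", "source_pos_mm", "orientations", "channel_labels",
            "channel_pos_mm")
  miss <- setdiff(need, names(lf))
  if (length(miss))
    stop("lead field is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- dim(lf$gains)
  if (length(d) != 3 || d[3] != 3)
    stop("lead field gains must be an n_channels x n_sources x 3 array",
         call. = FALSE)
  if (!all(is.finite(lf$gains)))
    stop("non-finite gains", call. = FALSE)
  if (d[1] < 8) stop("lead field needs at least 8 channels", call. = FALSE)
  if (d[2] < 100) stop("lead field needs at least 100 sources", call. = FALSE)
  if (!identical(dim(lf$source_pos_mm), c(d[2], 3L)) &&
      !identical(dim(lf$source_pos_mm), as.integer(c(d[2], 3))))
    stop("source_pos_mm shape mismatch", call. = FALSE)
  if (length(lf$channel_labels) != d[1])
    stop("channel_labels length mismatch", call. = FALSE)
  nrm <- sqrt(rowSums(lf$orientations^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("default orientations must have unit norm", call. = FALSE)
  invisible(lf)
}

#' Build an analytic spherical-head lead field
#'
#' Samples `n_sources` dipole locations uniformly inside a 75 mm sphere (kept
#' below the 80 mm inner-skull radius so the truncated Legendre series stays
#' accurate) and evaluates the three-shell analytic forward solution for unit
#' dipoles along x, y, z at every electrode of `montage`.  Each source's
#' channels-by-3 gain block is rescaled so that the largest attainable
#' absolute channel gain is 1; source amplitudes in microvolts are therefore
#' interpretable as best-channel scalp amplitudes.  Default orientations are
#' radial (they are re-derived per component by the simulator).
#'
#' @param montage montage name or label vector (see [standard_montage()]).
#' @param n_sources number of dipole sources (>= 100).
#' @param seed integer seed; the result is bit-identical for a fixed seed.
#' @param n_terms Legendre series truncation order.
#' @param max_source_radius_mm sources are sampled inside this radius.
#' @return an object of class `leadfield` with fields `gains`
#'   (channels x sources x 3), `source_pos_mm`, `orientations`,
#'   `channel_labels`, `channel_pos_mm`.
#' @export
build_spherical_leadfield <- function(montage = "biosemi64", n_sources = 8000,
                                      seed = 1, n_terms = 60,
                                      max_source_radius_mm = 75) {
  stopifnot(n_sources >= 100)
  mont <- standard_montage(montage)
  elec <- as.matrix(mont[, c("x", "y", "z")])
  set.seed(seed)
  # uniform in the ball: direction uniform on sphere, radius ~ U^(1/3)
  dir <- matrix(stats::rnorm(3 * n_sources), n_sources, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  rad <- max_source_radius_mm * stats::runif(n_sources)^(1 / 3)
  src <- dir * rad
  h <- .shell_coefficients(n_terms)
  gains <- array(0, dim = c(nrow(elec), n_sources, 3))
  for (j in seq_len(n_sources)) {
    G <- .dipole_gain(src[j, ], elec, n_terms = n_terms, h = h)
    sc <- max(sqrt(rowSums(G^2)))
    gains[, j, ] <- G / sc
  }
  lf <- structure(list(
    gains = gains,
    source_pos_mm = src,
    orientations = dir,          # radial defaults
    channel_labels = mont$label,
    channel_pos_mm = elec,
    n_terms = n_terms,
    geometry = spherical_head_geometry()), class = "leadfield")
  .validate_leadfield(lf)
  lf
}

#' @export
print.leadfield <- function(x, ...) {
  d <- dim(x$gains)
  cat(sprintf("<leadfield> %d channels x %d sources (three-shell sphere)\n",
              d[1], d[2]))
  invisible(x)
}

#' Persist / load a lead field
#'
#' The container is R native serialization (version 3) holding the exact
#' `leadfield` list; [load_leadfield()] re-validates every type invariant
#' (field presence, shapes, finite gains, unit-norm orientations) and fails
#' with a labeled error otherwise.
#' @param lf a `leadfield`.
#' @param path file path.
#' @export
write_leadfield <- function(lf, path) {
  .validate_leadfield(lf)
  saveRDS(unclass(lf), path, version = 3)
  invisible(path)
}

#' @rdname write_leadfield
#' @export
load_leadfield <- function(path) {
  obj <- readRDS(path)
  lf <- structure(obj, class = "leadfield")
  .validate_leadfield(lf)
  lf
}

#' Project dipole activity through the lead field
#'
#' Returns the per-channel gain vector of a unit dipole at source
#' `source_index` with moment direction `orientation`; scalp signal for a
#' source waveform `w(t)` is `gain %*% t(w)`.  The projection is linear in
#' the dipole moment.
#' @param lf a `leadfield`.
#' @param source_index integer source index.
#' @param orientation length-3 moment vector (need not be unit norm).
#' @return numeric vector of length n_channels.
#' @export
project_source <- function(lf, source_index, orientation) {
  drop(lf$gains[, source_index, ] %*% orientation)
}

#' Pick a random source near a center
#'
#' Uniformly random choice among the sources within `radius_mm` of
#' `center_mm`; `radius_mm = 0` degenerates to the single nearest source.
#' @param lf a `leadfield`.
#' @param center_mm length-3 center, mm.
#' @param radius_mm candidate radius, mm.
#' @param component_name label stored in the selection.
#' @return list with `component_name`, `source_index`, `center`, `radius`.
#' @export
pick_source_near <- function(lf, center_mm, radius_mm,
                             component_name = "component") {
  d <- sqrt(colSums((t(lf$source_pos_mm) - center_mm)^2))
  if (radius_mm <= 0) {
    idx <- which.min(d)
  } else {
    cand <- which(d <= radius_mm)
    if (!length(cand))
      stop(sprintf(
        "no source within %.1f mm of center (nearest available: %.1f mm)",
        radius_mm, min(d)), call. = FALSE)
    idx <- cand[sample.int(length(cand), 1)]
  }
  list(component_name = component_name, source_index = idx,
       center = center_mm, radius = radius_mm)
}

#' Pick spatially spaced sources
#'
#' Randomized best-candidate placement: starting from a random source, each
#' step draws a random batch of still-feasible candidates and keeps the one
#' farthest from the sources chosen so far.  This packs close to the
#' geometric limit while remaining random; after `max_restarts` failed
#' attempts an error reports the best achieved count.
#' @param lf a `leadfield`.
#' @param n number of sources.
#' @param min_spacing_mm minimum pairwise distance, mm.
#' @param max_restarts retry budget.
#' @param batch candidates examined per placement step.
#' @return integer vector of `n` source indices.
#' @export
pick_spaced_sources <- function(lf, n, min_spacing_mm, max_restarts = 50,
                                batch = 24) {
  stopifnot(n >= 1)
  pos <- lf$source_pos_mm
  d2min <- min_spacing_mm^2
  best <- 0
  for (r in seq_len(max_restarts)) {
    mind2 <- rep(Inf, nrow(pos))   # squared distance to nearest chosen
    chosen <- sample.int(nrow(pos), 1)
    while (length(chosen) < n) {
      i <- chosen[length(chosen)]
      d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2 +
        (pos[, 3] - pos[i, 3])^2
      mind2 <- pmin(mind2, d2)
      feas <- which(mind2 >= d2min)
      if (!length(feas)) break
      cand <- if (length(feas) > batch) sample(feas, batch) else feas
      chosen <- c(chosen, cand[which.max(mind2[cand])])
    }
    if (length(chosen) == n) return(chosen)
    best <- max(best, length(chosen))
  }
  stop(sprintf(
    "could not place %d sources %.1f mm apart (best achieved: %d)",
    n, min_spacing_mm, best), call. = FALSE)
}

#' Perturb an orientation by independent component scaling
#'
#' Each Cartesian component is multiplied by a factor drawn uniformly in
#' `[1 - dev_fraction, 1 + dev_fraction]`, then the vector is renormalized to
#' unit norm.  `dev_fraction = 0` returns the input unchanged.
#' @param orientation unit vector, length 3.
#' @param dev_fraction fraction in `[0, 1)`.
#' @return unit vector.
#' @export
orient_with_deviation <- function(orientation, dev_fraction = 0.2) {
  stopifnot(dev_fraction >= 0, dev_fraction < 1)
  if (dev_fraction == 0) return(orientation)
  v <- orientation * stats::runif(3, 1 - dev_fraction, 1 + dev_fraction)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) stop("degenerate zero-norm orientation", call. = FALSE)
  v / nrm
}

#' Orientation maximizing the gain magnitude at a channel
#'
#' Solved directly from the gain tensor: the 3-vector of channel gains for
#' unit dipoles along x/y/z, normalized, maximizes `|gain . orientation|`.
#' @param lf a `leadfield`.
#' @param source_index source index.
#' @param channel channel label (default `"Cz"`).
#' @return unit vector.
#' @export
best_orientation_at <- function(lf, source_index, channel = "Cz") {
  ch <- match(channel, lf$channel_labels)
  if (is.na(ch)) stop("unknown channel label: ", channel, call. = FALSE)
  g <- lf$gains[ch, source_index, ]
  nrm <- sqrt(sum(g^2))
  if (nrm < 1e-12) stop("source has no gain at channel ", channel,
                        call. = FALSE)
  g / nrm
}
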