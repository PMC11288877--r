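#' Standard electrode montages on an idealized spherical scalp
#'
#' Electrode positions are constructed geometrically on a sphere of the scalp
#' radius (92 mm): midline electrodes sit on the nasion-inion arc in 10%
#' (18 degree) steps, the outer 10-20 ring lies at 72 degrees inclination from
#' the vertex, and intermediate electrodes are placed by spherical
#' interpolation between the midline electrode of their row and the ring
#' electrode terminating the row.  This reproduces the familiar extended
#' 10-20 ("10-10") topology -- Cz at the vertex, FCz/Cz fronto-central --
#' without requiring a digitized cap file; coordinates are head-centered mm
#' with +x right, +y anterior, +z superior.
#'
#' @param montage one of `"biosemi64"` (the 64-channel BioSemi cap labelled in
#'   10-10 nomenclature) or `"wet8"` (the eight-channel montage FC1, FC2, C3,
#'   Cz, C4, CP1, CP2, Pz), or a character vector of 10-10 labels.
#' @param radius_mm scalp sphere radius in mm.
#' @return data.frame with columns `label`, `x`, `y`, `z` (mm).
#' @export
#' @examples
#' head(standard_montage("wet8"))
standard_montage <- function(montage = "biosemi64", radius_mm = 92) {
  if (length(montage) == 1 && montage %in% names(.montage_sets)) {
    labels <- .montage_sets[[montage]]
  } else {
    labels <- montage
  }
  pos <- t(vapply(labels, .electrode_unit_vector, numeric(3)))
  out <- data.frame(label = labels, x = pos[, 1] * radius_mm,
                    y = pos[, 2] * radius_mm, z = pos[, 3] * radius_mm,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.montage_sets <- list(
  biosemi64 = c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8",
    "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
    "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"),
  wet8 = c("FC1", "FC2", "C3", "Cz", "C4", "CP1", "CP2", "Pz")
)

# anterior-posterior angle of each row's midline crossing, degrees from the
# vertex (positive = towards nasion); rows Fp and O lie on the outer ring.
.row_angles <- c(Fp = 72, AF = 54, F = 36, FC = 18, C = 0, CP = -18,
                 P = -36, PO = -54, O = -72, I = -90)

.slerp <- function(a, b, f) {
  omega <- acos(max(-1, min(1, sum(a * b))))
  if (omega < 1e-12) return(a)
  (sin((1 - f) * omega) * a + sin(f * omega) * b) / sin(omega)
}

# unit vector of a 10-10 label on the unit sphere (see standard_montage)
.electrode_unit_vector <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3)
    stop("unknown channel label: ", label, call. = FALSE)
  row <- m[2]
  # temporal labels are the ring columns of the FC/C/CP rows
  col_raw <- m[3]
  temporal <- c(T = "C", TP = "CP", FT = "FC")
  if (row %in% names(temporal)) row <- temporal[[row]]
  if (!row %in% names(.row_angles))
    stop("unknown channel label: ", label, call. = FALSE)
  a <- .row_angles[[row]] * pi / 180
  midline <- c(0, sin(a), cos(a))
  if (col_raw == "z") return(midline)
  col <- as.integer(col_raw)
  side <- if (col %% 2 == 1) -1 else 1       # odd = left hemisphere
  k <- ceiling(col / 2)                      # arc fraction index (1..5)
  ring_az <- (pi / 2 - a)                    # ring azimuth from front midline
  ring <- c(side * sin(72 * pi / 180) * sin(ring_az),
            sin(72 * pi / 180) * cos(ring_az),
            cos(72 * pi / 180))
  if (abs(.row_angles[[row]]) == 72) {
    # Fp / O rows: electrodes sit on the outer ring, 18-degree steps from the
    # front (Fp) or back (O) midline crossing
    theta <- (18 * pi / 180) * k
    phi <- if (.row_angles[[row]] > 0) theta else pi - theta
    return(c(side * sin(72 * pi / 180) * sin(phi),
             sin(72 * pi / 180) * cos(phi),
             cos(72 * pi / 180)))
  }
  v <- .slerp(midline, ring, k / 4)
  v / sqrt(sum(v^2))
}
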