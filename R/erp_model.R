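# ---------------------------------------------------------------------------
# ERP class specifications: each experimental condition (error / correct) is a
# mixture of Gaussian peaks at cortical sources.  Trial-to-trial variability:
# every peak parameter (latency, width, amplitude) deviates by at most 20% of
# its value, sampled from a zero-mean truncated normal with sigma = max/3, and
# one epoch-wide latency shift (truncated normal, bound 100 ms) moves the
# whole ERP.  Peaks may be absent on a trial according to their probability.
# ---------------------------------------------------------------------------

#' Define an ERP component
#'
#' @param name component label (e.g. `"P320"`).
#' @param latency_ms peak center relative to the time-locking event.
#' @param width_ms full peak extent; the peak is rendered as a Gaussian with
#'   `sd = width_ms / 6` (the width spans +-3 sd).
#' @param amplitude_uv signed peak value at source level.
#' @param latency_dev,width_dev,amplitude_dev maximum deviation as a fraction
#'   of the nominal value (default 0.2).
#' @param probability chance that the peak is generated on a given trial.
#' @return list of class `erp_component`.
#' @export
erp_component <- function(name, latency_ms, width_ms, amplitude_uv,
                          latency_dev = 0.2, width_dev = 0.2,
                          amplitude_dev = 0.2, probability = 1) {
  stopifnot(width_ms > 0, probability >= 0, probability <= 1,
            latency_dev >= 0, width_dev >= 0, amplitude_dev >= 0)
  structure(list(name = name, latency_ms = latency_ms, width_ms = width_ms,
                 amplitude_uv = amplitude_uv, latency_dev = latency_dev,
                 width_dev = width_dev, amplitude_dev = amplitude_dev,
                 probability = probability), class = "erp_component")
}

.erp_class_spec <- function(name, components, global_shift_ms = 100,
                            source_centers_mm = NULL) {
  stopifnot(length(components) >= 1)
  structure(list(name = name, components = components,
                 global_shift_ms = global_shift_ms,
                 source_centers_mm = source_centers_mm,
                 source_bindings = NULL), class = "erp_class_spec")
}

# Default source centers: the interaction-error components localize to the
# medial fronto-central cortex (anterior cingulate / supplementary motor
# region), so their projections peak at FCz/Cz.  The coordinates below are
# synthetic defaults (head-centered mm on the midline, inside the source
# shell), configurable and not a literature localization.
.default_error_centers <- rbind(
  P200 = c(0, 30, 52),
  N250 = c(0, 22, 58),
  P320 = c(0, 12, 62),
  N450 = c(0, 2, 60))

.default_correct_centers <- rbind(
  P270 = c(0, 18, 60),
  P350 = c(0, 8, 62),
  N450 = c(0, 2, 60))

#' The error-condition ERP class (P200-N250-P320-N450 complex)
#'
#' Four components centered at 200/250/320/450 ms with source amplitudes
#' +20/-40/+50/-40 microvolts and widths 50/50/120/150 ms; every peak is
#' generated on every trial (probability 1), all deviations 0.2, epoch-wide
#' shift bound 100 ms.
#' @param source_centers_mm optional 4 x 3 matrix of component source centers.
#' @return an `erp_class_spec`.
#' @export
error_class_spec <- function(source_centers_mm = .default_error_centers) {
  comps <- list(
    erp_component("P200", 200, 50, 20),
    erp_component("N250", 250, 50, -40),
    erp_component("P320", 320, 120, 50),
    erp_component("N450", 450, 150, -40))
  .erp_class_spec("error", comps, 100, source_centers_mm)
}

#' The correct-condition ERP class (P270-N250-style complex)
#'
#' Two positive components at 270 ms (20 uV, width 200 ms) and 350 ms (10 uV,
#' width 250 ms) whose generation probabilities are drawn once per subject
#' uniformly in `[0.5, 1]`, plus a negative component at 450 ms (-40 uV,
#' width 150 ms) always present.  Consumes random numbers from the global
#' RNG stream for the probabilities.
#' @param source_centers_mm optional 3 x 3 matrix of component source centers.
#' @return an `erp_class_spec`.
#' @export
correct_class_spec <- function(source_centers_mm = .default_correct_centers) {
  p <- stats::runif(2, 0.5, 1)
  comps <- list(
    erp_component("P270", 270, 200, 20, probability = p[1]),
    erp_component("P350", 350, 250, 10, probability = p[2]),
    erp_component("N450", 450, 150, -40))
  .erp_class_spec("correct", comps, 100, source_centers_mm)
}

#' @export
print.erp_class_spec <- function(x, ...) {
  cat(sprintf("<erp_class_spec> '%s': %d components, shift bound %g ms\n",
              x$name, length(x$components), x$global_shift_ms))
  invisible(x)
}

# zero-mean truncated normal: |x| <= bound, sd = bound / 3 (the stated
# deviation is the maximum); bound 0 returns 0 exactly
.rtruncnorm_dev <- function(n, bound) {
  if (bound <= 0) return(rep(0, n))
  out <- stats::rnorm(n, 0, bound / 3)
  bad <- which(abs(out) > bound)
  tries <- 0
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), 0, bound / 3)
    bad <- bad[abs(out[bad]) > bound]
    tries <- tries + 1
    if (tries > 100) { out[bad] <- 0; break }
  }
  out
}

#' Sample one trial's realized ERP parameters
#'
#' Each component is independently present with its probability; latency,
#' width and amplitude are perturbed by truncated-normal deviations bounded
#' at `dev * |value|`; a single epoch-wide latency shift (truncated normal,
#' bounded at the class `global_shift_ms`) is added to every realized
#' latency.
#' @param spec an `erp_class_spec`.
#' @return list of class `realized_trial_erp` with fields `components`
#'   (data.frame: name, present, latency_ms, width_ms, amplitude_uv) and
#'   `shift_ms`.
#' @export
sample_trial <- function(spec) {
  nc <- length(spec$components)
  shift <- .rtruncnorm_dev(1, spec$global_shift_ms)
  present <- logical(nc); lat <- wid <- amp <- numeric(nc); nm <- character(nc)
  for (i in seq_len(nc)) {
    cm <- spec$components[[i]]
    nm[i] <- cm$name
    present[i] <- stats::runif(1) < cm$probability
    lat[i] <- cm$latency_ms +
      .rtruncnorm_dev(1, cm$latency_dev * abs(cm$latency_ms)) + shift
    amp[i] <- cm$amplitude_uv +
      .rtruncnorm_dev(1, cm$amplitude_dev * abs(cm$amplitude_uv))
    w <- cm$width_ms + .rtruncnorm_dev(1, cm$width_dev * cm$width_ms)
    retry <- 0
    while (w <= 0 && retry < 25) {
      w <- cm$width_ms + .rtruncnorm_dev(1, cm$width_dev * cm$width_ms)
      retry <- retry + 1
    }
    if (w <= 0) stop("could not realize a positive peak width", call. = FALSE)
    wid[i] <- w
  }
  structure(list(
    components = data.frame(name = nm, present = present, latency_ms = lat,
                            width_ms = wid, amplitude_uv = amp,
                            stringsAsFactors = FALSE),
    shift_ms = shift), class = "realized_trial_erp")
}

#' Render realized ERP components as source waveforms
#'
#' Each present component becomes a Gaussian pulse over `times_ms` with value
#' `amplitude_uv` at the realized center and `sd = width/6`; absent components
#' render as zeros.  Components are kept separate (one column each) because
#' every component projects through its own source.
#' @param realized a `realized_trial_erp`.
#' @param times_ms time axis in ms.
#' @return matrix `length(times_ms) x n_components`, microvolts.
#' @export
render_erp <- function(realized, times_ms) {
  cm <- realized$components
  out <- matrix(0, length(times_ms), nrow(cm))
  colnames(out) <- cm$name
  for (i in seq_len(nrow(cm))) {
    if (!cm$present[i]) next
    s <- cm$width_ms[i] / 6
    out[, i] <- cm$amplitude_uv[i] *
      exp(-((times_ms - cm$latency_ms[i])^2) / (2 * s^2))
  }
  out
}
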