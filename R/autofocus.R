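#' Dark-field gradient focus metric
#'
#' Computational dark-field sharpness measure used for holographic
#' autofocusing: the DC Fourier component of the complex field is zeroed
#' (optically, blocking the unscattered beam), the magnitude of the remaining
#' scattered field is taken, and the variance of its spatial gradient
#' magnitude is returned. For weakly scattering (phase) objects the scattered
#' field is tightly confined at the object plane and spreads with defocus, so
#' the metric is maximal in focus. It is invariant to adding a global
#' constant to the field and returns 0 for a constant field.
#'
#' @param field An [optical_field()] (or a complex/numeric matrix).
#' @return Non-negative scalar.
#' @export
focus_metric <- function(field) {
  v <- if (inherits(field, "optical_field")) field$values else field
  stopifnot(is.matrix(v))
  if (!is.complex(v)) v <- v + 0i
  dark <- Mod(v - mean(v))
  if (max(dark) == 0) return(0)
  gy <- dark[-1, , drop = FALSE] - dark[-nrow(dark), , drop = FALSE]
  gx <- dark[, -1, drop = FALSE] - dark[, -ncol(dark), drop = FALSE]
  g <- sqrt(gy[, -ncol(gy), drop = FALSE]^2 + gx[-nrow(gx), , drop = FALSE]^2)
  stats::var(as.vector(g))
}

# Vertex of the parabola through three (x, y) points; falls back to the
# middle x when the points are collinear. Supports non-uniform spacing.
parabola_vertex <- function(x, y) {
  d21 <- (y[2] - y[1]) / (x[2] - x[1])
  d32 <- (y[3] - y[2]) / (x[3] - x[2])
  a <- (d32 - d21) / (x[3] - x[1])
  if (a == 0) return(x[2])
  b <- d21 - a * (x[1] + x[2])
  -b / (2 * a)
}

# Shared scan engine: evaluate the focus metric over backpropagations of
# `amplitude` at the given effective distances and pitches, pick the maximum
# and refine it on the `axis` values by a parabola through the 3 neighbours.
# The metric is computed on a central crop (`margin` fraction per side):
# magnification rescaling and wrap-around leave z-independent sharp
# structure at the borders that would otherwise drown the focus peak.
scan_focus <- function(amplitude, z_eff_mm, pitch_um, axis, wavelength_nm,
                       pad, margin = 0.1) {
  stopifnot(length(z_eff_mm) == length(axis), length(z_eff_mm) >= 3)
  if (length(pitch_um) == 1) pitch_um <- rep(pitch_um, length(z_eff_mm))
  m <- as.integer(round(margin * min(dim(amplitude))))
  rows <- (1 + m):(nrow(amplitude) - m)
  cols <- (1 + m):(ncol(amplitude) - m)
  metric <- vapply(seq_along(z_eff_mm), function(i) {
    f <- optical_field(amplitude + 0i, pitch_um[i], wavelength_nm, "detector")
    u <- asm_propagate(f, -z_eff_mm[i], pad = pad)
    focus_metric(u$values[rows, cols])
  }, numeric(1))
  span <- max(metric) - min(metric)
  if (!is.finite(span) || span < 1e-6 * max(abs(metric), .Machine$double.eps)) {
    stop("no focus found: metric is flat over the scan range")
  }
  i <- which.max(metric)
  boundary <- i == 1L || i == length(axis)
  if (boundary) {
    warning("focus extremum on scan boundary; true focus may lie outside range")
    refined <- axis[i]
  } else {
    refined <- parabola_vertex(axis[(i - 1):(i + 1)], metric[(i - 1):(i + 1)])
    # keep the vertex inside the bracketing interval
    refined <- min(max(refined, axis[i - 1]), axis[i + 1])
  }
  structure(
    list(scan = tibble::tibble(z_mm = axis, metric = metric),
         best_mm = axis[i], refined_mm = refined, boundary = boundary),
    class = "focus_scan"
  )
}

#' @export
print.focus_scan <- function(x, ...) {
  cat(sprintf("<focus_scan> %d candidates, best %.3g mm, refined %.4g mm%s\n",
              nrow(x$scan), x$best_mm, x$refined_mm,
              if (x$boundary) " [boundary!]" else ""))
  invisible(x)
}

#' Autofocus by scanning backpropagation distances
#'
#' Backpropagates a normalized hologram amplitude over a coarse grid of
#' effective propagation distances, evaluates [focus_metric()] at each,
#' selects the extremum (maximum; polarity fixed by the synthetic recovery
#' suite and regression-tested) and refines it by parabolic interpolation
#' over the three neighbouring samples.
#'
#' @param amplitude Normalized hologram amplitude matrix (already at the
#'   pitch `pitch_um`, e.g. a rescaled burst image at the object pitch).
#' @param z_min_mm,z_max_mm Scan range of effective distances (mm).
#' @param step_mm Coarse scan step (mm), default 0.5 (half the 1 mm height
#'   spacing of the acquisition protocol).
#' @param pitch_um Sampling pitch (um/px).
#' @param wavelength_nm Wavelength (nm).
#' @param pad Zero-padding fraction for propagation.
#' @return A `focus_scan`: tibble of candidates and metric values plus
#'   `best_mm` (coarse), `refined_mm` (sub-step), and `boundary` flag (TRUE
#'   when the extremum sits on the scan boundary, suggesting the true focus
#'   lies outside the range).
#' @export
autofocus_scan <- function(amplitude, z_min_mm, z_max_mm, step_mm = 0.5,
                           pitch_um = 2, wavelength_nm = 561, pad = 0.25) {
  stopifnot(z_min_mm < z_max_mm, step_mm > 0)
  z <- seq(z_min_mm, z_max_mm, by = step_mm)
  scan_focus(amplitude, z, pitch_um, z, wavelength_nm, pad)
}

#' Autofocus on the nominal sample-to-camera distance scale
#'
#' Scans nominal `z2` candidates for a raw (un-rescaled) camera hologram of a
#' point-source recording. Each candidate is evaluated in its own plane-wave
#' equivalent: the camera grid reinterpreted at the candidate's object-plane
#' pitch `camera_pitch / M(z2)`, backpropagated by the candidate's effective
#' distance `z1 z2 / (z1 + z2)`. The extremum is refined on the `z2` axis.
#'
#' @param amplitude Normalized camera-grid hologram amplitude.
#' @param geometry An [acquisition_geometry()] (supplies `z1`, wavelength and
#'   camera pitch).
#' @param z2_min_mm,z2_max_mm,step_mm Scan range and step on the nominal
#'   distance axis (mm).
#' @param pad Zero-padding fraction.
#' @return A `focus_scan` whose distances are nominal `z2` (mm).
#' @export
autofocus_scan_nominal <- function(amplitude, geometry, z2_min_mm = 10,
                                   z2_max_mm = 25, step_mm = 0.5, pad = 0.25) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            z2_min_mm < z2_max_mm, step_mm > 0)
  z2 <- seq(z2_min_mm, z2_max_mm, by = step_mm)
  eg <- effective_geometry(geometry$z1_mm, z2, geometry$camera_pitch_um)
  scan_focus(amplitude, eg$z_eff_mm, eg$object_pitch_um, z2,
             geometry$wavelength_nm, pad)
}

#' Consensus autofocus of a rescaled multi-height burst
#'
#' Scans every height of a burst (already rescaled to the reference
#' magnification) on the nominal-distance axis and combines the K per-height
#' estimates into one consistent set of focus distances. The stage steps
#' between heights are known exactly from the geometry, so only the common
#' offset is free: each height's refined distance votes for the offset and
#' the median vote wins, making the result robust to a single height's scan
#' locking onto a spurious sharpness peak.
#'
#' @param burst A rescaled [hologram_burst()] (see
#'   [rescale_burst_to_reference()]).
#' @param geometry An [acquisition_geometry()].
#' @param z2_min_mm,z2_max_mm,step_mm Scan range and step on the nominal
#'   distance axis (mm).
#' @param pad Padding fraction for the scan backpropagations.
#' @param normalize_sigma Passed to [normalize_hologram()].
#' @return Numeric vector of K refined effective focus distances (mm),
#'   strictly increasing, with the per-height raw scan estimates attached as
#'   attribute `"per_height_z2_mm"`.
#' @export
autofocus_burst <- function(burst, geometry, z2_min_mm = 10, z2_max_mm = 25,
                            step_mm = 0.5, pad = 0.25,
                            normalize_sigma = NULL) {
  stopifnot(inherits(burst, "hologram_burst"),
            inherits(geometry, "acquisition_geometry"))
  if (length(burst$images) != geometry$K) {
    stop("burst size does not match geometry K")
  }
  z2_grid <- seq(z2_min_mm, z2_max_mm, by = step_mm)
  z_eff_grid <- effective_geometry(geometry$z1_mm, z2_grid)$z_eff_mm
  p1 <- geometry_table(geometry)$object_pitch_um[1]
  z2_hat <- vapply(seq_along(burst$images), function(k) {
    amp <- normalize_hologram(burst$images[[k]], sigma = normalize_sigma)
    sc <- scan_focus(amp, z_eff_grid, p1, z2_grid, geometry$wavelength_nm,
                     pad)
    sc$refined_mm
  }, numeric(1))
  offsets <- geometry$z2_mm - geometry$z2_mm[1]
  z2_first <- stats::median(z2_hat - offsets)
  out <- effective_geometry(geometry$z1_mm, z2_first + offsets)$z_eff_mm
  attr(out, "per_height_z2_mm") <- z2_hat
  out
}
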