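#' Optical field carrier
#'
#' An `optical_field` is the package's carrier of a scalar complex field
#' sampled on a regular 2D grid: a complex matrix plus the physical sampling
#' pitch and the illumination wavelength. All propagation and retrieval
#' routines consume and return this object.
#'
#' Internally the package works in micrometres for every length: the
#' constructor converts the wavelength from nanometres once, at the module
#' boundary, and propagation distances given in millimetres are converted by
#' the functions that accept them.
#'
#' @param values Complex (or real, promoted to complex) matrix of field
#'   amplitudes. Row index is y, column index is x (row-major image
#'   convention).
#' @param pitch_um Sampling pitch in micrometres per pixel (square pixels).
#' @param wavelength_nm Illumination wavelength in nanometres.
#' @param plane_label Free-text label of the plane the field lives in.
#' @return An object of class `optical_field` with elements `values`,
#'   `pitch_um`, `wavelength_um`, `plane_label`.
#' @examples
#' f <- optical_field(matrix(1 + 0i, 64, 64), pitch_um = 2, wavelength_nm = 561)
#' dim(f$values)
#' @export
optical_field <- function(values, pitch_um, wavelength_nm,
                          plane_label = "unlabeled") {
  if (!is.matrix(values) || length(values) == 0L) {
    stop("`values` must be a non-empty matrix")
  }
  if (!is.complex(values)) {
    if (!is.numeric(values)) stop("`values` must be numeric or complex")
    values <- values + 0i
  }
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || pitch_um <= 0) {
    stop("`pitch_um` must be a single positive number")
  }
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1L ||
      wavelength_nm <= 0) {
    stop("`wavelength_nm` must be a single positive number")
  }
  structure(
    list(values = values, pitch_um = pitch_um,
         wavelength_um = wavelength_nm / 1000, plane_label = plane_label),
    class = "optical_field"
  )
}

#' @export
print.optical_field <- function(x, ...) {
  cat(sprintf(
    "<optical_field> %d x %d px, pitch %.4g um, lambda %.4g nm [%s]\n",
    nrow(x$values), ncol(x$values), x$pitch_um, 1000 * x$wavelength_um,
    x$plane_label))
  invisible(x)
}

#' Acquisition geometry of a multi-height lensless recording
#'
#' Bundles the physical parameters of the in-line point-source recording:
#' source-to-sample distance `z1`, the K nominal sample-to-camera distances
#' `z2`, the wavelength and the camera pixel pitch. The distances follow the
#' published protocol by default: a burst of five holograms at sample-camera
#' distances 15 to 19 mm in 1 mm steps, a source-camera distance of about
#' 15 cm (hence `z1_mm = 135` at the first height) and a 561 nm laser.
#'
#' @param z1_mm Source-to-sample distance in mm (> 0).
#' @param z2_mm Vector of K sample-to-camera distances in mm, strictly
#'   increasing, all positive; K >= 2 for multi-height retrieval.
#' @param wavelength_nm Wavelength in nm.
#' @param camera_pitch_um Camera pixel pitch in micrometres. The published
#'   system does not state its sensor pitch; 2.0 um is a plumbing default for
#'   the simulator, not a reported value.
#' @return An `acquisition_geometry` object.
#' @examples
#' geom <- acquisition_geometry()
#' geom$z2_mm
#' @export
acquisition_geometry <- function(z1_mm = 135, z2_mm = 15:19,
                                 wavelength_nm = 561, camera_pitch_um = 2.0) {
  if (z1_mm <= 0) stop("invalid geometry: z1_mm must be > 0")
  if (any(z2_mm <= 0)) stop("invalid geometry: all z2_mm must be > 0")
  if (length(z2_mm) >= 2 && any(diff(z2_mm) <= 0)) {
    stop("invalid geometry: z2_mm must be strictly increasing")
  }
  if (camera_pitch_um <= 0 || wavelength_nm <= 0) {
    stop("invalid geometry: pitch and wavelength must be > 0")
  }
  structure(
    list(z1_mm = z1_mm, z2_mm = as.numeric(z2_mm),
         wavelength_nm = wavelength_nm, camera_pitch_um = camera_pitch_um,
         K = length(z2_mm)),
    class = "acquisition_geometry"
  )
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(
    "<acquisition_geometry> z1 = %g mm, z2 = [%s] mm, lambda = %g nm, pitch = %g um\n",
    x$z1_mm, paste(x$z2_mm, collapse = ", "), x$wavelength_nm,
    x$camera_pitch_um))
  invisible(x)
}

#' Plane-wave equivalent of a point-source recording geometry
#'
#' A diverging spherical wave from a point source at distance `z1` before the
#' sample, recorded at distance `z2` behind it, is equivalent to plane-wave
#' illumination with transverse magnification `M = (z1 + z2) / z1` and an
#' effective propagation distance `z_eff = z1 * z2 / (z1 + z2)`. The package
#' handles spherical illumination exclusively through this equivalence: no
#' explicit spherical phase factor is ever propagated.
#'
#' The object-plane sampling pitch is the camera pitch demagnified by `M`.
#'
#' @param z1_mm Source-to-sample distance in mm (> 0).
#' @param z2_mm Sample-to-camera distance(s) in mm (>= 0); vectorised.
#' @param camera_pitch_um Optional camera pitch; when given, the object-plane
#'   pitch is included in the result.
#' @return A tibble with one row per `z2_mm`: `z2_mm`, `magnification`,
#'   `z_eff_mm`, and `object_pitch_um` (NA when no pitch given).
#' @examples
#' effective_geometry(135, 15) # M ~ 1.111, z_eff = 13.5 mm
#' @export
effective_geometry <- function(z1_mm, z2_mm, camera_pitch_um = NA_real_) {
  if (!is.numeric(z1_mm) || length(z1_mm) != 1L || z1_mm <= 0) {
    stop("invalid geometry: z1_mm must be a single positive number")
  }
  if (any(z2_mm < 0)) stop("invalid geometry: z2_mm must be >= 0")
  m <- (z1_mm + z2_mm) / z1_mm
  tibble::tibble(
    z2_mm = as.numeric(z2_mm),
    magnification = m,
    z_eff_mm = z1_mm * z2_mm / (z1_mm + z2_mm),
    object_pitch_um = camera_pitch_um / m
  )
}

#' Effective geometry table for a full acquisition
#'
#' @param geometry An [acquisition_geometry()].
#' @return Tibble with one row per burst height (see [effective_geometry()]).
#' @export
geometry_table <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  effective_geometry(geometry$z1_mm, geometry$z2_mm, geometry$camera_pitch_um)
}

#' Invert the plane-wave equivalence
#'
#' Maps an effective propagation distance back to the nominal sample-to-camera
#' distance for a given source distance: `z2 = z1 * z_eff / (z1 - z_eff)`.
#' Used to report autofocus results on the nominal distance scale.
#'
#' @param z1_mm Source-to-sample distance in mm.
#' @param z_eff_mm Effective distance(s) in mm, each < `z1_mm`.
#' @return Nominal `z2` distance(s) in mm.
#' @export
z2_from_zeff <- function(z1_mm, z_eff_mm) {
  stopifnot(z1_mm > 0, all(z_eff_mm < z1_mm))
  z1_mm * z_eff_mm / (z1_mm - z_eff_mm)
}
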