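#' Normalize a hologram to unit background amplitude
#'
#' Converts recorded intensity counts to field amplitude `sqrt(I / B)` where
#' `B` is a smooth background estimate: a wide Gaussian blur of the intensity
#' (default), or the global mean when `sigma = 0`. The result has background
#' close to 1, the level against which the positive absorption constraint is
#' later enforced, and is invariant to global intensity rescaling.
#'
#' @param image Numeric matrix of intensities (>= 0, not all zero).
#' @param sigma Gaussian blur radius in pixels for the background estimate;
#'   `0` uses the global mean. Default: 1/8 of the smaller image dimension.
#' @return Amplitude matrix with background approximately 1.
#' @export
normalize_hologram <- function(image, sigma = NULL) {
  stopifnot(is.matrix(image))
  if (any(image < 0)) stop("intensities must be non-negative")
  if (all(image == 0)) stop("cannot normalize an all-zero hologram")
  if (is.null(sigma)) sigma <- min(dim(image)) / 8
  if (sigma > 0) {
    b <- EBImage::gblur(image, sigma = sigma, boundary = "replicate")
    # Guard against blur undershoot near dark regions.
    b[b < .Machine$double.eps] <- mean(image)
  } else {
    b <- mean(image)
  }
  sqrt(image / b)
}

#' Positive absorption constraint
#'
#' Object-plane constraint of the retrieval: cells absorb light or are
#' transparent, they never amplify, so the transmittance amplitude may not
#' exceed the (unit) background. Wherever `|U| > 1` the amplitude is reset to
#' 1 and the phase kept. Idempotent.
#'
#' @param values Complex matrix (object-plane field).
#' @return Complex matrix with amplitude capped at 1.
#' @export
apply_pac <- function(values) {
  a <- Mod(values)
  over <- a > 1
  if (any(over)) values[over] <- values[over] / a[over]
  values
}

# Reconstructed fields carry an arbitrary global phase (the ASM kernel's
# on-axis term exp(i 2 pi z / lambda)); anchor the background at zero phase
# so phase maps are directly thresholdable.
remove_piston <- function(values) {
  values * exp(-1i * Arg(mean(values)))
}

new_phase_reconstruction <- function(phase, amplitude, focus_z_eff_mm,
                                     pitch_um, wavelength_nm, method,
                                     residuals = numeric(0)) {
  structure(
    list(phase = phase, amplitude = amplitude,
         focus_z_eff_mm = focus_z_eff_mm, pitch_um = pitch_um,
         wavelength_nm = wavelength_nm, method = method,
         residuals = residuals),
    class = "phase_reconstruction"
  )
}

#' @export
print.phase_reconstruction <- function(x, ...) {
  cat(sprintf(
    "<phase_reconstruction> %s, %d x %d px, phase range [%.3f, %.3f] rad\n",
    x$method, nrow(x$phase), ncol(x$phase), min(x$phase), max(x$phase)))
  invisible(x)
}

#' One-line summary of a reconstruction
#'
#' @param x A `phase_reconstruction`.
#' @param ... Unused.
#' @return A one-row tibble: method, grid size, number of sweeps, final data
#'   fidelity residual, phase range.
#' @export
glance.phase_reconstruction <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_row = nrow(x$phase), n_col = ncol(x$phase),
    n_sweeps = length(x$residuals),
    final_residual = if (length(x$residuals)) utils::tail(x$residuals, 1)
                     else NA_real_,
    phase_min = min(x$phase), phase_max = max(x$phase)
  )
}

#' Single-height backpropagation baseline
#'
#' Backpropagates one normalized hologram amplitude (zero phase) to the
#' object plane. With only one intensity measurement the conjugate
#' (twin-image) term cannot be separated, so this baseline shows the
#' out-of-focus twin artifact that multi-height retrieval suppresses.
#'
#' @param amplitude Normalized amplitude matrix (see [normalize_hologram()]).
#' @param z_eff_mm Effective propagation distance to the object plane (mm).
#' @param pitch_um Object-plane sampling pitch (um/px).
#' @param wavelength_nm Wavelength (nm).
#' @param pad Zero-padding fraction for propagation.
#' @return A `phase_reconstruction` (method `"backprop"`).
#' @export
backpropagate_single <- function(amplitude, z_eff_mm, pitch_um,
                                 wavelength_nm = 561, pad = 0.25) {
  f <- optical_field(amplitude, pitch_um, wavelength_nm, "detector")
  obj <- asm_propagate(f, -z_eff_mm, pad = pad)
  obj$values <- remove_piston(obj$values)
  new_phase_reconstruction(Arg(obj$values), Mod(obj$values), z_eff_mm,
                           pitch_um, wavelength_nm, "backprop")
}

#' Multi-height Gerchberg-Saxton retrieval with positive absorption constraint
#'
#' Iterative phase retrieval over K holograms of one scene recorded at K
#' distances. One sweep: propagate the current field estimate sequentially
#' through detector planes 1 to K, replacing the amplitude with the measured
#' one at each plane while keeping the evolving phase; backpropagate from
#' plane K to the object plane and apply the positive absorption constraint
#' (amplitude capped at the unit background, [apply_pac()]); propagate to
#' plane 1 and measure the data-fidelity residual (mean absolute amplitude
#' mismatch) before re-imposing the plane-1 amplitude. The returned object
#' field is the final object-plane iterate after a last constraint
#' application, so its amplitude never exceeds 1.
#'
#' Iteration stops after `n_iter` sweeps, or earlier on a residual plateau
#' (relative change < 1e-4 over 3 sweeps) or once the fidelity has not
#' improved for 3 consecutive sweeps (the constrained iteration settles into
#' a small limit cycle around its fixed point). The returned field is always
#' the best iterate by data fidelity and the residual history is reported up
#' to it; a residual growing by more than 10% over 5 sweeps additionally
#' raises a divergence warning.
#'
#' @param burst A [hologram_burst()], already rescaled to a common
#'   magnification ([rescale_burst_to_reference()]); K >= 2.
#' @param focus_z_eff_mm K effective focus distances (mm), strictly
#'   increasing (object-plane equivalents of the nominal heights, typically
#'   from [autofocus_scan()] or [geometry_table()]).
#' @param pitch_um Object-plane pitch (um/px); defaults to the pitch recorded
#'   on the rescaled burst.
#' @param wavelength_nm Wavelength (nm).
#' @param n_iter Maximum number of sweeps (>= 1), default 30.
#' @param pad Zero-padding fraction used for every propagation.
#' @param normalize_sigma Passed to [normalize_hologram()].
#' @return A `phase_reconstruction` (method `"gs_pac"`) with the per-sweep
#'   residual history.
#' @export
gs_pac_reconstruct <- function(burst, focus_z_eff_mm, pitch_um = NULL,
                               wavelength_nm = 561, n_iter = 30, pad = 0.25,
                               normalize_sigma = NULL) {
  stopifnot(inherits(burst, "hologram_burst"))
  k_planes <- length(burst$images)
  if (k_planes < 2) stop("multi-height retrieval needs K >= 2 holograms")
  if (length(focus_z_eff_mm) != k_planes) {
    stop("need one focus distance per hologram")
  }
  if (any(diff(focus_z_eff_mm) <= 0)) {
    stop("focus distances must be strictly increasing")
  }
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(pitch_um)) pitch_um <- burst$object_pitch_um
  if (is.null(pitch_um)) stop("object-plane pitch unknown; pass `pitch_um`")

  amps <- lapply(burst$images, normalize_hologram, sigma = normalize_sigma)
  field <- optical_field(amps[[1]] + 0i, pitch_um, wavelength_nm, "plane 1")
  z <- focus_z_eff_mm
  residuals <- numeric(0)
  best_obj <- NULL; best_res <- Inf; best_sweep <- 0L
  obj <- NULL

  for (sweep in seq_len(n_iter)) {
    for (k in seq_len(k_planes)[-1]) {
      field <- asm_propagate(field, z[k] - z[k - 1], pad = pad)
      a <- Mod(field$values)
      ph <- field$values / ifelse(a > 0, a, 1)
      field$values <- amps[[k]] * ph
    }
    obj <- asm_propagate(field, -z[k_planes], pad = pad)
    obj$values <- apply_pac(obj$values)
    field <- asm_propagate(obj, z[1], pad = pad)
    res <- mean(abs(Mod(field$values) - amps[[1]]))
    residuals <- c(residuals, res)
    if (res < best_res) { best_res <- res; best_obj <- obj; best_sweep <- sweep }
    a <- Mod(field$values)
    ph <- field$values / ifelse(a > 0, a, 1)
    field$values <- amps[[1]] * ph
    n <- length(residuals)
    if (n >= 6 && residuals[n] > 1.1 * residuals[n - 5]) {
      warning("retrieval residual diverging; returning best iterate")
      obj <- best_obj
      residuals <- residuals[seq_len(best_sweep)]
      break
    }
    # stop once the data fidelity has ceased improving (GS with a hard
    # object constraint settles into a small limit cycle around its fixed
    # point) or on a flat plateau; keep the best iterate either way
    if (sweep - best_sweep >= 3) {
      obj <- best_obj
      residuals <- residuals[seq_len(best_sweep)]
      break
    }
    if (n >= 4) {
      recent <- residuals[(n - 3):n]
      if (max(abs(diff(recent))) < 1e-4 * max(recent[1], .Machine$double.eps)) {
        break
      }
    }
  }
  # the returned field is always the best iterate by data fidelity
  obj <- best_obj
  residuals <- residuals[seq_len(best_sweep)]
  obj$values <- apply_pac(remove_piston(obj$values))
  new_phase_reconstruction(Arg(obj$values), Mod(obj$values), z, pitch_um,
                           wavelength_nm, "gs_pac", residuals)
}
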