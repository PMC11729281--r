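# Angular-spectrum free-space propagation.
#
# The transfer function is evaluated on the centered FFT frequency grid and
# cached per (shape, pitch, wavelength, distance) because iterative retrieval
# re-propagates over the same few distances hundreds of times.

.kernel_cache <- new.env(parent = emptyenv())

#' FFT sample frequencies
#'
#' Cyclic frequencies for an n-point DFT with sample spacing `d`, in FFT
#' order (DC first, negative frequencies in the upper half).
#'
#' @param n Number of samples.
#' @param d Sample spacing.
#' @return Numeric vector of length `n` in cycles per unit of `d`.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# Band-limited angular spectrum transfer function H(fx, fy; z) in FFT order.
# Evanescent components (lambda^2 (fx^2 + fy^2) > 1) are zeroed.
asm_transfer <- function(n_row, n_col, pitch_um, wavelength_um, dz_um) {
  key <- paste(n_row, n_col, pitch_um, wavelength_um, dz_um, sep = "|")
  h <- .kernel_cache[[key]]
  if (!is.null(h)) return(h)
  fy <- fft_freq(n_row, pitch_um)
  fx <- fft_freq(n_col, pitch_um)
  arg <- 1 - outer((wavelength_um * fy)^2, (wavelength_um * fx)^2, `+`)
  band <- arg >= 0
  kz <- matrix(0, n_row, n_col)
  kz[band] <- sqrt(arg[band])
  h <- exp((2i * pi / wavelength_um) * dz_um * kz)
  h[!band] <- 0i
  if (length(.kernel_cache) > 64) {
    rm(list = ls(.kernel_cache), envir = .kernel_cache)
  }
  assign(key, h, envir = .kernel_cache)
  h
}

# Squared radial frequency grid in FFT order, cached (reused by the alias
# check on every propagation).
freq_radius2 <- function(n_row, n_col, pitch_um) {
  key <- paste("f2", n_row, n_col, pitch_um, sep = "|")
  f2 <- .kernel_cache[[key]]
  if (is.null(f2)) {
    f2 <- outer(fft_freq(n_row, pitch_um)^2, fft_freq(n_col, pitch_um)^2, `+`)
    assign(key, f2, envir = .kernel_cache)
  }
  f2
}

# Pad with the median border value (not zero): optical fields carry a
# non-zero background, and a zero pad would act as a hard aperture whose
# diffraction ringing contaminates the whole grid.
pad_matrix <- function(m, margin, fill = NULL) {
  if (margin == 0L) return(m)
  if (is.null(fill)) {
    border <- c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)])
    fill <- complex(real = stats::median(Re(border)),
                    imaginary = stats::median(Im(border)))
  }
  out <- matrix(fill, nrow(m) + 2L * margin, ncol(m) + 2L * margin)
  out[margin + seq_len(nrow(m)), margin + seq_len(ncol(m))] <- m
  out
}

crop_matrix <- function(m, margin, n_row, n_col) {
  if (margin == 0L) return(m)
  m[margin + seq_len(n_row), margin + seq_len(n_col)]
}

#' Propagate an optical field through free space
#'
#' Angular-spectrum method: the field's spectrum is multiplied by the exact
#' scalar free-space transfer function
#' `H = exp(i 2 pi / lambda * z * sqrt(1 - (lambda fx)^2 - (lambda fy)^2))`
#' on the propagating band; evanescent components are zeroed. A negative
#' distance back-propagates. The kernel is unimodular on the band, so
#' propagation conserves power exactly when no padding is applied.
#'
#' The field may be padded by a fractional margin per side before the
#' transform and cropped afterwards to suppress wrap-around of the
#' diffraction chirp; the pad is filled with the median border value so the
#' background continues smoothly instead of forming a hard aperture. Set
#' `pad = 0` for strictly unitary (cyclic) propagation.
#'
#' @param field An [optical_field()].
#' @param dz_mm Signed propagation distance in millimetres.
#' @param pad Fractional zero-padding per side (default 0.25).
#' @return The propagated [optical_field()].
#' @examples
#' f <- optical_field(matrix(1 + 0i, 32, 32), 2, 561)
#' g <- asm_propagate(f, 5, pad = 0)
#' max(abs(abs(g$values) - 1)) < 1e-12
#' @export
asm_propagate <- function(field, dz_mm, pad = 0.25) {
  stopifnot(inherits(field, "optical_field"), is.finite(dz_mm), pad >= 0)
  if (dz_mm == 0) return(field)
  dz_um <- dz_mm * 1000
  v <- field$values
  nr <- nrow(v); nc <- ncol(v)
  margin <- as.integer(round(pad * min(nr, nc)))
  vp <- pad_matrix(v, margin)
  h <- asm_transfer(nrow(vp), ncol(vp), field$pitch_um, field$wavelength_um,
                    dz_um)
  sp <- stats::fft(vp)
  # The sampled kernel chirp aliases at spatial frequencies beyond
  # f_a = N pitch / (2 lambda |z|); warn only when the field actually carries
  # power out there (smooth fields at typical distances never trigger this).
  f_alias <- min(nrow(vp), ncol(vp)) * field$pitch_um /
    (2 * field$wavelength_um * abs(dz_um))
  f2 <- freq_radius2(nrow(vp), ncol(vp), field$pitch_um)
  p_alias <- sum(abs(sp[f2 > f_alias^2])^2)
  # Threshold chosen loose (1% of total power): the formal kernel-sampling
  # bound is very conservative for weakly scattering scenes, whose energy is
  # concentrated at DC; only gross violations (sharp structures at long
  # distances on small grids) should surface.
  if (p_alias > 0.01 * sum(abs(sp)^2)) {
    warning(sprintf(
      "field has %.2g of its power beyond the alias-free band for |z| = %.3g mm; increase padding or grid size",
      p_alias / sum(abs(sp)^2), abs(dz_mm)))
  }
  out <- stats::fft(sp * h, inverse = TRUE) / length(vp)
  optical_field(crop_matrix(out, margin, nr, nc), field$pitch_um,
                field$wavelength_um * 1000,
                plane_label = sprintf("%s %+g mm", field$plane_label, dz_mm))
}
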