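#' Multi-height hologram burst
#'
#' One acquisition timestamp of the multiplexed lensless system: K intensity
#' holograms of the same scene recorded at K sample-to-camera distances
#' (the published protocol uses K = 5, distances 15-19 mm).
#'
#' @param images List of K numeric matrices (intensity counts, >= 0), all of
#'   identical shape.
#' @param z2_mm Numeric vector of K nominal sample-to-camera distances (mm).
#' @param timestamp_min Acquisition time in minutes.
#' @param channel_id Channel label.
#' @return A `hologram_burst` object.
#' @export
hologram_burst <- function(images, z2_mm, timestamp_min = 0,
                           channel_id = "ch0") {
  if (!is.list(images) || length(images) == 0L) {
    stop("`images` must be a non-empty list of matrices")
  }
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1])) stop("all images in a burst must share one shape")
  if (length(z2_mm) != length(images)) {
    stop("`z2_mm` must have one distance per image")
  }
  if (any(vapply(images, function(m) any(m < 0), logical(1)))) {
    stop("hologram intensities must be non-negative")
  }
  structure(
    list(images = images, z2_mm = as.numeric(z2_mm),
         timestamp_min = timestamp_min, channel_id = channel_id,
         rescaled = FALSE),
    class = "hologram_burst"
  )
}

#' @export
print.hologram_burst <- function(x, ...) {
  cat(sprintf(
    "<hologram_burst> K = %d, %d x %d px, z2 = [%s] mm, t = %g min, channel %s%s\n",
    length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
    paste(x$z2_mm, collapse = ", "), x$timestamp_min, x$channel_id,
    if (isTRUE(x$rescaled)) " (rescaled)" else ""))
  invisible(x)
}

# Catmull-Rom cubic convolution weights (a = -1/2) for fractional offset t.
cubic_weights <- function(t) {
  cbind(((-t + 2) * t - 1) * t / 2,
        ((3 * t - 5) * t * t + 2) / 2,
        ((-3 * t + 4) * t + 1) * t / 2,
        (t - 1) * t * t / 2)
}

# n_out x n_in interpolation matrix sampling at (possibly off-grid) positions
# `src` (1-based, clamped to the edge).
cubic_interp_matrix <- function(src, n_in) {
  i0 <- floor(src)
  t <- src - i0
  w <- cubic_weights(t)
  m <- matrix(0, length(src), n_in)
  for (k in -1:2) {
    idx <- pmin(pmax(i0 + k, 1L), n_in)
    m[cbind(seq_along(src), idx)] <- m[cbind(seq_along(src), idx)] + w[, k + 2]
  }
  m
}

#' Rescale an image about its centre
#'
#' Separable bicubic (Catmull-Rom) zoom by `factor` about the pixel-centred
#' image midpoint; output keeps the input shape, edges replicate. Values are
#' clipped at 0 (intensities cannot be negative).
#'
#' @param image Numeric matrix.
#' @param factor Zoom factor (> 0); a feature `d` pixels wide becomes
#'   `d * factor` pixels wide.
#' @return Matrix of the same shape.
#' @export
rescale_image <- function(image, factor) {
  stopifnot(is.matrix(image), factor > 0)
  if (factor == 1) return(image)
  nr <- nrow(image); nc <- ncol(image)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  src_y <- cy + (seq_len(nr) - cy) / factor
  src_x <- cx + (seq_len(nc) - cx) / factor
  out <- cubic_interp_matrix(src_y, nr) %*% image %*%
    t(cubic_interp_matrix(src_x, nc))
  out[out < 0] <- 0
  out
}

#' Rescale a burst to a common magnification
#'
#' Each height of a point-source recording sees the object at a slightly
#' different magnification `M_k = (z1 + z2_k) / z1` (about 1.3% spread over
#' the 15-19 mm protocol). Before multi-height retrieval every hologram is
#' resampled by `M_ref / M_k` onto the grid of the reference (first) height so
#' that all K images share one object-plane pitch.
#'
#' @param burst A [hologram_burst()].
#' @param geometry An [acquisition_geometry()] resolving one magnification per
#'   image.
#' @return A [hologram_burst()] flagged `rescaled`, carrying the shared
#'   `magnification` and `object_pitch_um` of the reference height.
#' @export
rescale_burst_to_reference <- function(burst, geometry) {
  stopifnot(inherits(burst, "hologram_burst"),
            inherits(geometry, "acquisition_geometry"))
  if (length(burst$images) != geometry$K) {
    stop("burst size does not match geometry K")
  }
  gt <- geometry_table(geometry)
  m_ref <- gt$magnification[1]
  factors <- m_ref / gt$magnification
  out <- burst
  out$images <- purrr::map2(burst$images, factors, rescale_image)
  out$rescaled <- TRUE
  out$magnification <- m_ref
  out$object_pitch_um <- gt$object_pitch_um[1]
  out$scale_factors <- factors
  out
}

# Sub-pixel translation estimate of `image` relative to `ref` by FFT
# cross-correlation with parabolic refinement of the integer peak.
estimate_shift <- function(ref, image) {
  a <- ref - mean(ref); b <- image - mean(image)
  xc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
  nr <- nrow(xc); nc <- ncol(xc)
  refine <- function(center, minus, plus) {
    den <- minus - 2 * center + plus
    if (den == 0) 0 else 0.5 * (minus - plus) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dy <- refine(xc[pk[1], pk[2]], xc[wrap(pk[1] - 1, nr), pk[2]],
               xc[wrap(pk[1] + 1, nr), pk[2]])
  dx <- refine(xc[pk[1], pk[2]], xc[pk[1], wrap(pk[2] - 1, nc)],
               xc[pk[1], wrap(pk[2] + 1, nc)])
  sy <- pk[1] - 1 + dy; sx <- pk[2] - 1 + dx
  if (sy > nr / 2) sy <- sy - nr
  if (sx > nc / 2) sx <- sx - nc
  c(dy = sy, dx = sx)
}

# Cyclic sub-pixel shift via a Fourier phase ramp.
shift_image <- function(image, dy, dx) {
  nr <- nrow(image); nc <- ncol(image)
  py <- exp(-2i * pi * fft_freq(nr) * dy)
  px <- exp(-2i * pi * fft_freq(nc) * dx)
  out <- Re(stats::fft(stats::fft(image) * outer(py, px), inverse = TRUE)) /
    length(image)
  out[out < 0] <- 0
  out
}

#' Register burst images to the first height
#'
#' Optional lateral alignment applied after rescaling: each image is shifted
#' (sub-pixel, Fourier) to maximise its cross-correlation with the reference
#' image, compensating stage drift between heights.
#'
#' @param burst A [hologram_burst()].
#' @return The burst with images aligned to the first; estimated shifts are
#'   stored in `$shifts` (rows = images, columns dy/dx in pixels).
#' @export
register_burst <- function(burst) {
  stopifnot(inherits(burst, "hologram_burst"))
  ref <- burst$images[[1]]
  shifts <- matrix(0, length(burst$images), 2,
                   dimnames = list(NULL, c("dy", "dx")))
  for (k in seq_along(burst$images)[-1]) {
    s <- estimate_shift(ref, burst$images[[k]])
    shifts[k, ] <- s
    if (any(abs(s) > 1e-3)) {
      burst$images[[k]] <- shift_image(burst$images[[k]], s[1], s[2])
    }
  }
  burst$shifts <- shifts
  burst
}
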