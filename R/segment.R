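# Phase-map segmentation: fixed-threshold binarization, 8-connected
# labeling, physical-area size classes.

# 8-connected labeling. EBImage::bwlabel is 4-connected, so labels touching
# only diagonally are merged afterwards with a union-find pass.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lm <- EBImage::bwlabel(mask != 0)
  lm <- matrix(as.integer(lm), nrow(lm), ncol(lm))
  n <- max(lm)
  if (n < 2) return(lm)
  nr <- nrow(lm); nc <- ncol(lm)
  pairs <- rbind(
    cbind(as.vector(lm[-nr, -nc]), as.vector(lm[-1, -1])),   # down-right
    cbind(as.vector(lm[-nr, -1]), as.vector(lm[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relabel <- integer(n)
  relabel[sort(unique(root))] <- seq_along(unique(root))
  out <- lm
  out[lm > 0] <- relabel[root[lm[lm > 0]]]
  out
}

#' Binarize a reconstructed phase map
#'
#' Thresholds the phase above a fixed level, mirroring the published
#' procedure of a manually chosen threshold held constant across the whole
#' experiment and all channels. The background is optionally flattened by
#' subtracting the median phase first, and connected components smaller than
#' `min_pixels` (8-connectivity) are removed to suppress speckle.
#'
#' @param phase Numeric matrix of phase values (radians).
#' @param threshold Phase threshold (radians), default 0.5.
#' @param min_pixels Minimum component size kept, default 4.
#' @param flatten Subtract the median phase before thresholding (default TRUE).
#' @return Logical mask matrix.
#' @export
binarize_phase <- function(phase, threshold = 0.5, min_pixels = 4,
                           flatten = TRUE) {
  stopifnot(is.matrix(phase), is.finite(threshold), min_pixels >= 0)
  if (flatten) phase <- phase - stats::median(phase)
  mask <- phase > threshold
  if (min_pixels > 0 && any(mask)) {
    lm <- label_components(mask)
    sizes <- tabulate(lm[lm > 0])
    keep <- which(sizes >= min_pixels)
    mask <- matrix(lm %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Classify objects by physical area
#'
#' Three size classes on the object area: single cells up to 23 um^2, small
#' unseparated clusters between 23 and 46 um^2, and large clusters above
#' 46 um^2. The lower boundary is inclusive for the smaller class
#' (`single <= 23 < small_cluster <= 46 < large_cluster`): a cell of exactly
#' 23 um^2 is a single cell.
#'
#' @param area_um2 Numeric vector of object areas in um^2 (> 0).
#' @param bounds Two class boundaries in um^2, default `c(23, 46)`.
#' @return Factor with levels `single`, `small_cluster`, `large_cluster`.
#' @examples
#' classify_by_area(c(10, 30, 60))
#' @export
classify_by_area <- function(area_um2, bounds = c(23, 46)) {
  if (any(!is.finite(area_um2)) || any(area_um2 <= 0)) {
    stop("areas must be positive and finite")
  }
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  cut(area_um2, breaks = c(0, bounds, Inf),
      labels = c("single", "small_cluster", "large_cluster"),
      right = TRUE)
}

#' Label a mask and measure objects in physical units
#'
#' 8-connected component labeling followed by per-object measurement:
#' pixel-count area converted to um^2 via the object-plane pitch, unweighted
#' pixel centroid in um (pixel centres at `(index - 0.5) * pitch`), and the
#' size class of [classify_by_area()].
#'
#' @param mask Logical/binary matrix.
#' @param object_pitch_um Object-plane sampling pitch (um/px, > 0).
#' @param timestamp_min Frame acquisition time (minutes).
#' @param threshold_used Threshold recorded for provenance (radians).
#' @param bounds Area class boundaries (um^2).
#' @return A `segmented_frame`: list with the integer `label_map` and an
#'   `objects` tibble (`object_id`, `x_um`, `y_um`, `area_um2`, `size_class`).
#' @export
label_and_measure <- function(mask, object_pitch_um, timestamp_min = 0,
                              threshold_used = NA_real_, bounds = c(23, 46)) {
  stopifnot(is.matrix(mask), object_pitch_um > 0)
  lm <- label_components(mask)
  n <- max(lm)
  if (n == 0) {
    objects <- tibble::tibble(object_id = integer(0), x_um = numeric(0),
                              y_um = numeric(0), area_um2 = numeric(0),
                              size_class = classify_by_area(numeric(0) + 1)[0])
  } else {
    idx <- which(lm > 0)
    lab <- lm[idx]
    row_i <- ((idx - 1) %% nrow(lm)) + 1
    col_i <- ((idx - 1) %/% nrow(lm)) + 1
    npx <- tabulate(lab, n)
    objects <- tibble::tibble(
      object_id = seq_len(n),
      x_um = (as.numeric(tapply(col_i, lab, mean)) - 0.5) * object_pitch_um,
      y_um = (as.numeric(tapply(row_i, lab, mean)) - 0.5) * object_pitch_um,
      area_um2 = npx * object_pitch_um^2,
      size_class = classify_by_area(npx * object_pitch_um^2, bounds)
    )
  }
  structure(
    list(label_map = lm, objects = objects, threshold_used = threshold_used,
         timestamp_min = timestamp_min, object_pitch_um = object_pitch_um),
    class = "segmented_frame"
  )
}

#' @export
print.segmented_frame <- function(x, ...) {
  cat(sprintf("<segmented_frame> t = %g min, %d objects (%s)\n",
              x$timestamp_min, nrow(x$objects),
              paste(table(x$objects$size_class), collapse = "/")))
  invisible(x)
}

#' Tidy a segmented frame into its object table
#'
#' @param x A `segmented_frame`.
#' @param ... Unused.
#' @return The `objects` tibble with the timestamp added.
#' @export
tidy.segmented_frame <- function(x, ...) {
  dplyr::mutate(x$objects, timestamp_min = x$timestamp_min, .before = 1)
}

#' Segment a phase reconstruction
#'
#' Convenience wrapper chaining [binarize_phase()] and [label_and_measure()]
#' on a `phase_reconstruction`.
#'
#' @param recon A `phase_reconstruction`.
#' @param threshold,min_pixels,flatten Passed to [binarize_phase()].
#' @param bounds Passed to [label_and_measure()].
#' @param timestamp_min Frame time (minutes).
#' @return A `segmented_frame`.
#' @export
segment_phase <- function(recon, threshold = 0.5, min_pixels = 4,
                          flatten = TRUE, bounds = c(23, 46),
                          timestamp_min = 0) {
  stopifnot(inherits(recon, "phase_reconstruction"))
  mask <- binarize_phase(recon$phase, threshold, min_pixels, flatten)
  label_and_measure(mask, recon$pitch_um, timestamp_min, threshold, bounds)
}
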