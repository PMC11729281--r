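# TIFF and configuration I/O.
#
# Encoding conventions (the TIFF writer stores values in [0, 1]):
#   holograms  - 16-bit grayscale, value = counts / 65535
#   phase      - float32, value = (phase + pi) / (2 pi), phase in (-pi, pi]
#   amplitude  - float32, value = amplitude / 2 (amplitudes stay below 2)

#' Write / read a 16-bit hologram TIFF
#'
#' @param counts Matrix of intensity counts in 0..65535.
#' @param path File path.
#' @return `read_hologram_tiff` returns the counts matrix.
#' @export
write_hologram_tiff <- function(counts, path) {
  stopifnot(is.matrix(counts), all(counts >= 0), all(counts <= 65535))
  tiff::writeTIFF(counts / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_hologram_tiff
#' @export
read_hologram_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  round(m * 65535)
}

#' Write / read float32 phase and amplitude maps
#'
#' Phase maps in (-pi, pi] radians are stored affinely as
#' `(phase + pi) / (2 pi)`; amplitudes as `amplitude / 2`. The readers invert
#' the encoding.
#'
#' @param phase,amplitude Numeric matrices.
#' @param path File path.
#' @export
write_phase_tiff <- function(phase, path) {
  stopifnot(all(phase > -pi - 1e-9), all(phase <= pi + 1e-9))
  tiff::writeTIFF(pmin(pmax((phase + pi) / (2 * pi), 0), 1), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_phase_tiff
#' @export
read_phase_tiff <- function(path) {
  tiff::readTIFF(path) * 2 * pi - pi
}

#' @rdname write_phase_tiff
#' @export
write_amplitude_tiff <- function(amplitude, path) {
  stopifnot(all(amplitude >= 0), all(amplitude <= 2))
  tiff::writeTIFF(amplitude / 2, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_phase_tiff
#' @export
read_amplitude_tiff <- function(path) {
  tiff::readTIFF(path) * 2
}

#' Read a burst from a channel directory
#'
#' Expects the dialect written by [make_experiment()]:
#' `<dir>/t<frame %04d>_h<height>.tif`, one file per height.
#'
#' @param dir Channel directory.
#' @param frame Timestamp index (1-based).
#' @param geometry An [acquisition_geometry()] (supplies the distances).
#' @param frame_interval_min Minutes per timestamp.
#' @return A [hologram_burst()].
#' @export
read_burst_dir <- function(dir, frame, geometry,
                           frame_interval_min = 5) {
  paths <- file.path(dir, sprintf("t%04d_h%d.tif", frame,
                                  seq_len(geometry$K)))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing burst files: ", paste(paths[missing], collapse = ", "))
  }
  hologram_burst(lapply(paths, read_hologram_tiff), geometry$z2_mm,
                 timestamp_min = (frame - 1) * frame_interval_min,
                 channel_id = basename(dir))
}

# Count the timestamps present in a channel directory.
count_timestamps <- function(dir) {
  length(unique(sub("_h[0-9]+\\.tif$", "", dir(dir, pattern = "^t[0-9]+_h[0-9]+\\.tif$"))))
}
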