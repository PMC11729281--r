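# Synthetic-data generator: persistent-random-walk cell cultures rendered as
# physically consistent multi-height in-line hologram bursts, with ground
# truth for every downstream stage.

# Run `expr` under a private RNG stream, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a moving cell culture
#'
#' Persistent random walk: each cell keeps a heading that diffuses by
#' Gaussian increments of standard deviation `turn_sigma` per frame while the
#' step length is exactly `speed_um_per_min * frame_interval_min`. Cells
#' reflect off a margin inside the field of view. Identical seeds give
#' identical scenes.
#'
#' Cell geometry emulates the imaged cultures: Gaussian phase/absorption
#' bumps whose half-maximum radius defaults to 2.7 um, so the half-peak
#' footprint is about 23 um^2, the single-cell area of the published
#' experiment. Peak phase (1 rad) and absorption are plumbing defaults for a
#' weakly scattering, purely passive object (transmittance <= 1); the real
#' cultures' optical thickness is not reported.
#'
#' @param n_cells Number of cells (>= 0).
#' @param speed_um_per_min Migration speed (um/min, >= 0).
#' @param n_frames Number of frames.
#' @param fov_um Field of view side length (um).
#' @param turn_sigma Heading diffusion per frame (radians), default 0.3.
#' @param frame_interval_min Frame interval (minutes), default 5 (one burst
#'   every 5 minutes, as acquired).
#' @param radius_um Half-maximum radius of the cell bump (um), default 2.7.
#' @param peak_phase Peak phase delay (radians), default 1.
#' @param absorption Peak absorbance (dimensionless, >= 0), default 0.1.
#' @param margin_um Reflecting margin from the FOV edge (um), default 25.
#' @param seed Integer seed.
#' @return A `sim_scene`: `positions` tibble (`frame`, `cell_id`, `x_um`,
#'   `y_um`), `cells` tibble (per-cell optical parameters), and metadata.
#' @export
generate_scene <- function(n_cells, speed_um_per_min = 0.2, n_frames = 10,
                           fov_um = 512, turn_sigma = 0.3,
                           frame_interval_min = 5, radius_um = 2.7,
                           peak_phase = 1, absorption = 0.1, margin_um = 25,
                           seed = 1) {
  if (n_cells < 0) stop("n_cells must be >= 0")
  if (speed_um_per_min < 0) stop("speed must be >= 0")
  stopifnot(n_frames >= 1, fov_um > 2 * margin_um)
  step <- speed_um_per_min * frame_interval_min
  lo <- margin_um; hi <- fov_um - margin_um
  pos <- with_seed(seed, {
    if (n_cells == 0) {
      tibble::tibble(frame = integer(0), cell_id = integer(0),
                     x_um = numeric(0), y_um = numeric(0))
    } else {
      x <- stats::runif(n_cells, lo, hi)
      y <- stats::runif(n_cells, lo, hi)
      heading <- stats::runif(n_cells, 0, 2 * pi)
      out <- vector("list", n_frames)
      out[[1]] <- cbind(x, y)
      for (f in seq_len(n_frames)[-1]) {
        heading <- heading + stats::rnorm(n_cells, 0, turn_sigma)
        x <- x + step * cos(heading)
        y <- y + step * sin(heading)
        # reflect off the walls, flipping the heading component
        fx_lo <- x < lo; fx_hi <- x > hi
        x[fx_lo] <- 2 * lo - x[fx_lo]; x[fx_hi] <- 2 * hi - x[fx_hi]
        heading[fx_lo | fx_hi] <- pi - heading[fx_lo | fx_hi]
        fy_lo <- y < lo; fy_hi <- y > hi
        y[fy_lo] <- 2 * lo - y[fy_lo]; y[fy_hi] <- 2 * hi - y[fy_hi]
        heading[fy_lo | fy_hi] <- -heading[fy_lo | fy_hi]
        out[[f]] <- cbind(x, y)
      }
      tibble::tibble(
        frame = rep(seq_len(n_frames), each = n_cells),
        cell_id = rep(seq_len(n_cells), n_frames),
        x_um = unlist(lapply(out, function(m) m[, 1])),
        y_um = unlist(lapply(out, function(m) m[, 2]))
      )
    }
  })
  structure(
    list(
      positions = pos,
      cells = tibble::tibble(cell_id = seq_len(n_cells),
                             radius_um = radius_um, peak_phase = peak_phase,
                             absorption = absorption,
                             speed_um_per_min = speed_um_per_min),
      fov_um = fov_um, n_frames = n_frames,
      frame_interval_min = frame_interval_min, turn_sigma = turn_sigma,
      seed = seed
    ),
    class = "sim_scene"
  )
}

#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf(
    "<sim_scene> %d cells, %d frames @ %g min, FOV %g um, seed %d\n",
    nrow(x$cells), x$n_frames, x$frame_interval_min, x$fov_um, x$seed))
  invisible(x)
}

#' Number of timestamps in a time-lapse of a given duration
#'
#' One burst is acquired at time zero and then every `interval_min` minutes:
#' a 68.5 h experiment at the protocol's 5-minute cadence yields 823
#' timestamps.
#'
#' @param duration_h Experiment duration in hours.
#' @param interval_min Burst interval in minutes (default 5).
#' @return Integer timestamp count.
#' @export
n_timestamps <- function(duration_h, interval_min = 5) {
  stopifnot(duration_h >= 0, interval_min > 0)
  as.integer(floor(duration_h * 60 / interval_min) + 1)
}

# Smallest grid size >= n whose FFT factorises into small primes (and whose
# 1.5x padded size does too).
next_fft_size <- function(n) {
  smooth <- function(k) {
    for (p in c(2L, 3L, 5L, 7L)) while (k %% p == 0L) k <- k %/% p
    k == 1L
  }
  n <- as.integer(n)
  while (!(smooth(n) && (n %% 2L == 0L) && smooth(as.integer(1.5 * n)))) {
    n <- n + 1L
  }
  n
}

# Accumulate Gaussian bumps (peak `height`, half-maximum radius `radius_um`)
# at physical positions onto a grid sampled at `pitch_um`, centred on the
# physical point `center_um` (the optical axis). Each bump is evaluated on a
# +/-4 sigma window only.
add_bumps <- function(grid, xy_um, pitch_um, radius_um, height,
                      center_um = c(0, 0)) {
  if (nrow(xy_um) == 0) return(grid)
  sigma_px <- (radius_um / sqrt(2 * log(2))) / pitch_um
  w <- ceiling(4 * sigma_px)
  nr <- nrow(grid); nc <- ncol(grid)
  for (i in seq_len(nrow(xy_um))) {
    cx <- (xy_um[i, 1] - center_um[1]) / pitch_um + (nc + 1) / 2
    cy <- (xy_um[i, 2] - center_um[2]) / pitch_um + (nr + 1) / 2
    c0 <- max(1L, floor(cx - w)); c1 <- min(nc, ceiling(cx + w))
    r0 <- max(1L, floor(cy - w)); r1 <- min(nr, ceiling(cy + w))
    if (c0 > c1 || r0 > r1) next
    dy2 <- (r0:r1 - cy)^2
    dx2 <- (c0:c1 - cx)^2
    grid[r0:r1, c0:c1] <- grid[r0:r1, c0:c1] +
      height[i] * exp(-outer(dy2, dx2, `+`) / (2 * sigma_px^2))
  }
  grid
}

#' Ground-truth object transmittance of one scene frame
#'
#' The complex transmittance `t = exp(-A) * exp(i * Phi)` of the scene at a
#' given frame, sampled at `pitch_um`: A and Phi are sums of per-cell
#' Gaussian bumps. `|t| <= 1` everywhere, consistent with the positive
#' absorption constraint.
#'
#' The grid is centred on the optical axis, which pierces the scene at its
#' physical centre `(fov/2, fov/2)`: magnification acts about the axis, so
#' the per-height object grids of one burst must share this anchor.
#'
#' @param scene A [generate_scene()] result.
#' @param frame Frame index.
#' @param pitch_um Sampling pitch (um/px).
#' @param n_px Grid side length in pixels.
#' @return List with complex `values`, `phase` and `absorbance` matrices.
#' @export
scene_transmittance <- function(scene, frame, pitch_um, n_px) {
  stopifnot(inherits(scene, "sim_scene"))
  pos <- scene$positions[scene$positions$frame == frame, , drop = FALSE]
  pos <- dplyr::arrange(pos, .data$cell_id)
  cells <- scene$cells[match(pos$cell_id, scene$cells$cell_id), , drop = FALSE]
  xy <- cbind(pos$x_um, pos$y_um)
  center <- c(scene$fov_um / 2, scene$fov_um / 2)
  zero <- matrix(0, n_px, n_px)
  if (nrow(xy)) {
    phi <- add_bumps(zero, xy, pitch_um, cells$radius_um[1], cells$peak_phase,
                     center)
    ab <- add_bumps(zero, xy, pitch_um, cells$radius_um[1], cells$absorption,
                    center)
  } else {
    phi <- zero; ab <- zero
  }
  list(values = exp(-ab) * exp(1i * phi), phase = phi, absorbance = ab)
}

#' Map scene coordinates into the reconstruction frame
#'
#' Reconstructed frames are measured on the reference-height object grid,
#' whose pixel `(i, j)` centre lies at `((j - 0.5) p1, (i - 0.5) p1)` um.
#' This helper translates ground-truth scene positions into that frame (a
#' constant offset: both frames are axis-centred but the grid origin is its
#' corner), enabling direct comparison with segmentation output.
#'
#' @param scene A [generate_scene()] result.
#' @param geometry An [acquisition_geometry()].
#' @param n_px Grid size used for rendering/reconstruction.
#' @return The scene `positions` tibble with `x_um`/`y_um` shifted into the
#'   reconstruction frame.
#' @export
scene_object_positions <- function(scene, geometry, n_px) {
  p1 <- geometry_table(geometry)$object_pitch_um[1]
  offset <- n_px * p1 / 2 - scene$fov_um / 2
  dplyr::mutate(scene$positions, x_um = .data$x_um + offset,
                y_um = .data$y_um + offset)
}

#' Render a multi-height hologram burst of one scene frame
#'
#' Forward model of the lensless recording. The cells are static within a
#' burst (the five heights are captured seconds apart while the cells move at
#' most ~1 px/min). The scene transmittance is sampled once at the
#' reference-height object pitch `camera_pitch / M_1`, propagated by each
#' height's effective distance `z_eff_k` (angular spectrum, cyclic: the
#' simulated culture continues periodically outside the FOV), and squared to
#' intensity; the height-dependent magnification is then applied exactly as
#' the spherical illumination does optically, by geometrically magnifying
#' the diffraction pattern onto the fixed camera grid (factor `M_k / M_1`).
#' Gaussian shot noise (variance `I / photons`) plus additive read noise are
#' applied and the result is quantised to 16-bit counts at `gain` counts per
#' unit intensity.
#'
#' @param scene A [generate_scene()] result.
#' @param frame Frame index.
#' @param geometry An [acquisition_geometry()].
#' @param photons Photons per unit intensity for shot noise; `Inf` (noiseless)
#'   disables it. Default 10000 (1% background noise).
#' @param read_noise Additive noise standard deviation in intensity units,
#'   default 0.002.
#' @param gain Counts per unit intensity, default 20000.
#' @param pad Propagation padding fraction; the default 0 propagates
#'   cyclically, which is seamless for the unit background (the simulated
#'   culture behaves as if periodically continued outside the FOV).
#' @param seed Integer seed for the noise draw (derived per frame when
#'   rendering sequences).
#' @param n_px Grid side length in pixels; the default covers the full scene
#'   FOV at every height (smallest FFT-friendly size at the finest
#'   object-plane pitch).
#' @return A [hologram_burst()] of K 16-bit count images.
#' @export
render_burst <- function(scene, frame, geometry, photons = 10000,
                         read_noise = 0.002, gain = 20000, pad = 0,
                         seed = 1, n_px = NULL) {
  stopifnot(inherits(scene, "sim_scene"),
            inherits(geometry, "acquisition_geometry"))
  gt <- geometry_table(geometry)
  p1 <- gt$object_pitch_um[1]
  if (is.null(n_px)) n_px <- next_fft_size(ceiling(scene$fov_um / p1))
  tr <- scene_transmittance(scene, frame, p1, n_px)
  f <- optical_field(tr$values, p1, geometry$wavelength_nm, "object")
  images <- with_seed(seed, {
    lapply(seq_len(geometry$K), function(k) {
      u <- asm_propagate(f, gt$z_eff_mm[k], pad = pad)
      intensity <- rescale_image(Mod(u$values)^2,
                                 gt$magnification[k] / gt$magnification[1])
      if (is.finite(photons)) {
        intensity <- intensity +
          sqrt(intensity / photons) * stats::rnorm(length(intensity))
      }
      if (read_noise > 0) {
        intensity <- intensity + read_noise * stats::rnorm(length(intensity))
      }
      matrix(pmin(65535, pmax(0, round(intensity * gain))), n_px, n_px)
    })
  })
  hologram_burst(images, gt$z2_mm, timestamp_min = (frame - 1) *
                   scene$frame_interval_min, channel_id = "sim")
}

#' Write a full synthetic multi-channel experiment to disk
#'
#' Emulates an N-channel acquisition: per channel one persistent-random-walk
#' culture rendered as per-timestamp multi-height bursts in the directory
#' dialect `<channel>/t<frame>_h<height>.tif` (16-bit grayscale), plus
#' ground-truth CSVs (`ground_truth/positions.csv`, `cells.csv`,
#' `channels.csv`) and the geometry configuration (`config.yaml`).
#'
#' @param out_dir Output directory (must be empty unless `force`).
#' @param channels Tibble/data.frame with columns `label`, `speed_um_per_min`,
#'   `n_cells`.
#' @param n_frames Timestamps per channel.
#' @param geometry An [acquisition_geometry()].
#' @param fov_um Field of view (um).
#' @param seed Top-level seed; per-channel and per-frame seeds derive from it.
#' @param force Overwrite a non-empty directory.
#' @param ... Passed to [generate_scene()] / [render_burst()].
#' @return Invisibly, a manifest list (paths, channel table, seed).
#' @export
make_experiment <- function(out_dir, channels, n_frames,
                            geometry = acquisition_geometry(), fov_um = 512,
                            seed = 1, force = FALSE, ...) {
  channels <- tibble::as_tibble(channels)
  stopifnot(all(c("label", "speed_um_per_min", "n_cells") %in% names(channels)))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE)")
  }
  dir.create(file.path(out_dir, "ground_truth"), recursive = TRUE,
             showWarnings = FALSE)
  dots <- list(...)
  scene_args <- dots[names(dots) %in% names(formals(generate_scene))]
  render_args <- dots[names(dots) %in%
                        setdiff(names(formals(render_burst)),
                                c("scene", "frame", "geometry", "seed"))]
  all_pos <- list(); all_cells <- list()
  for (ci in seq_len(nrow(channels))) {
    label <- channels$label[ci]
    ch_dir <- file.path(out_dir, label)
    dir.create(ch_dir, showWarnings = FALSE)
    scene <- do.call(generate_scene, c(
      list(n_cells = channels$n_cells[ci],
           speed_um_per_min = channels$speed_um_per_min[ci],
           n_frames = n_frames, fov_um = fov_um,
           seed = seed * 1000L + ci), scene_args))
    for (f in seq_len(n_frames)) {
      burst <- do.call(render_burst, c(
        list(scene = scene, frame = f, geometry = geometry,
             seed = seed * 1000L + ci * 100000L + f), render_args))
      for (k in seq_along(burst$images)) {
        write_hologram_tiff(burst$images[[k]],
                            file.path(ch_dir, sprintf("t%04d_h%d.tif", f, k)))
      }
    }
    all_pos[[ci]] <- dplyr::mutate(scene$positions, channel = label,
                                   .before = 1)
    all_cells[[ci]] <- dplyr::mutate(scene$cells, channel = label, .before = 1)
  }
  utils::write.csv(dplyr::bind_rows(all_pos),
                   file.path(out_dir, "ground_truth", "positions.csv"),
                   row.names = FALSE)
  utils::write.csv(dplyr::bind_rows(all_cells),
                   file.path(out_dir, "ground_truth", "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(channels,
                   file.path(out_dir, "ground_truth", "channels.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(
    wavelength_nm = geometry$wavelength_nm, z1_mm = geometry$z1_mm,
    z2_mm = geometry$z2_mm, camera_pitch_um = geometry$camera_pitch_um,
    fov_um = fov_um, n_frames = n_frames, seed = seed
  ), file.path(out_dir, "config.yaml"))
  invisible(list(out_dir = out_dir, channels = channels, seed = seed,
                 n_frames = n_frames))
}
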