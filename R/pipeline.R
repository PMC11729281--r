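# End-to-end orchestration: N independent channels through rescale ->
# autofocus -> retrieval -> segmentation -> tracking -> comparison.

#' Default experiment configuration
#'
#' All defaults reproduce the published acquisition protocol: 561 nm
#' illumination, five sample-to-camera distances 15-19 mm in 1 mm steps with
#' a 135 mm source-to-sample distance, bursts every 5 minutes, area class
#' bounds 23 and 46 um^2, and a 50-frame (250 min) speed window. The camera
#' pitch (2 um) and the phase threshold (0.5 rad) are plumbing defaults; the
#' publication does not state them.
#'
#' @param ... Named overrides merged into the nested default list, e.g.
#'   `retrieval = list(iters = 10)`.
#' @return A validated `experiment_config` (nested named list).
#' @export
default_config <- function(...) {
  cfg <- list(
    geometry = list(wavelength_nm = 561, z1_mm = 135,
                    z2_mm = c(15, 16, 17, 18, 19), camera_pitch_um = 2),
    retrieval = list(iters = 30, register = TRUE, pad = 0.25,
                     normalize_sigma = NULL),
    segmentation = list(threshold = 0.5, min_pixels = 4,
                        area_bounds = c(23, 46), flatten = TRUE),
    tracking = list(gate_um = 20, window_frames = 50, interval_min = 5,
                    memory_frames = 3, classes = "single",
                    smooth_frames = 20),
    autofocus = list(enabled = TRUE, z2_min = 10, z2_max = 25, step = 0.5)
  )
  overrides <- list(...)
  for (blk in names(overrides)) {
    stopifnot(blk %in% names(cfg))
    for (key in names(overrides[[blk]])) {
      if (!key %in% names(cfg[[blk]])) stop("unknown config key: ",
                                            blk, "$", key)
      cfg[[blk]][[key]] <- overrides[[blk]][[key]]
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  g <- cfg$geometry
  if (g$wavelength_nm <= 0) stop("config: wavelength_nm must be > 0")
  if (g$z1_mm <= 0) stop("config: z1_mm must be > 0")
  if (any(g$z2_mm <= 0) || (length(g$z2_mm) > 1 && any(diff(g$z2_mm) <= 0))) {
    stop("config: z2_mm must be positive and strictly increasing")
  }
  if (g$camera_pitch_um <= 0) stop("config: camera_pitch_um must be > 0")
  if (cfg$retrieval$iters < 1) stop("config: retrieval iters must be >= 1")
  sb <- cfg$segmentation$area_bounds
  if (length(sb) != 2 || sb[1] >= sb[2]) {
    stop("config: area_bounds must be two increasing values")
  }
  tr <- cfg$tracking
  if (tr$gate_um <= 0 || tr$window_frames < 2 || tr$interval_min <= 0) {
    stop("config: invalid tracking block")
  }
  structure(cfg, class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return `config_from_yaml` returns an `experiment_config`.
#' @export
config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, raw)
}

#' @rdname config_from_yaml
#' @param cfg An `experiment_config`.
#' @export
config_to_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_geometry <- function(cfg) {
  acquisition_geometry(cfg$geometry$z1_mm, cfg$geometry$z2_mm,
                       cfg$geometry$wavelength_nm,
                       cfg$geometry$camera_pitch_um)
}

#' Burst sources for the pipeline
#'
#' A burst source tells [run_pipeline()] how to obtain the burst of each
#' timestamp for one channel: from a directory of TIFFs
#' (`burst_source_dir()`, the on-disk dialect of [make_experiment()]) or
#' rendered on the fly from a simulated scene (`burst_source_sim()`, which
#' avoids materialising hundreds of bursts).
#'
#' @param dir Channel directory.
#' @param geometry An [acquisition_geometry()].
#' @param n_frames Number of timestamps (directory sources count the files).
#' @param frame_interval_min Minutes per timestamp.
#' @return A `burst_source`: list with `n_frames` and `get(frame)`.
#' @export
burst_source_dir <- function(dir, geometry, n_frames = NULL,
                             frame_interval_min = 5) {
  if (is.null(n_frames)) n_frames <- count_timestamps(dir)
  structure(list(
    n_frames = n_frames,
    label = basename(dir),
    get = function(frame) read_burst_dir(dir, frame, geometry,
                                         frame_interval_min)
  ), class = "burst_source")
}

#' @rdname burst_source_dir
#' @param scene A [generate_scene()] result.
#' @param seed Base seed for per-frame noise draws.
#' @param ... Passed to [render_burst()] (noise, gain, pad).
#' @export
burst_source_sim <- function(scene, geometry, seed = 1, ...) {
  dots <- list(...)
  structure(list(
    n_frames = scene$n_frames,
    label = "sim",
    get = function(frame) {
      do.call(render_burst, c(list(scene = scene, frame = frame,
                                   geometry = geometry,
                                   seed = seed + 7919L * frame), dots))
    }
  ), class = "burst_source")
}

# Consensus autofocus of the first rescaled burst of a channel; nominal
# geometry when disabled.
pipeline_autofocus <- function(burst, cfg, geometry) {
  if (!isTRUE(cfg$autofocus$enabled)) return(geometry_table(geometry)$z_eff_mm)
  as.numeric(autofocus_burst(burst, geometry, cfg$autofocus$z2_min,
                             cfg$autofocus$z2_max, cfg$autofocus$step,
                             pad = cfg$retrieval$pad,
                             normalize_sigma = cfg$retrieval$normalize_sigma))
}

# One channel: reconstruct + segment every timestamp, then track.
run_channel <- function(source, cfg, geometry, verbose = FALSE) {
  z_eff <- NULL
  detections <- vector("list", source$n_frames)
  counts <- vector("list", source$n_frames)
  for (f in seq_len(source$n_frames)) {
    burst <- source$get(f)
    burst <- rescale_burst_to_reference(burst, geometry)
    if (isTRUE(cfg$retrieval$register)) burst <- register_burst(burst)
    if (is.null(z_eff)) z_eff <- pipeline_autofocus(burst, cfg, geometry)
    recon <- gs_pac_reconstruct(
      burst, z_eff, wavelength_nm = geometry$wavelength_nm,
      n_iter = cfg$retrieval$iters, pad = cfg$retrieval$pad,
      normalize_sigma = cfg$retrieval$normalize_sigma)
    seg <- segment_phase(recon, cfg$segmentation$threshold,
                         cfg$segmentation$min_pixels,
                         cfg$segmentation$flatten,
                         cfg$segmentation$area_bounds,
                         timestamp_min = burst$timestamp_min)
    obj <- seg$objects
    counts[[f]] <- dplyr::count(obj, .data$size_class, .drop = FALSE) |>
      dplyr::mutate(frame = f, .before = 1)
    obj <- obj[obj$size_class %in% cfg$tracking$classes, , drop = FALSE]
    if (nrow(obj)) {
      detections[[f]] <- tibble::tibble(frame = f, x_um = obj$x_um,
                                        y_um = obj$y_um)
    }
    if (verbose && f %% 25 == 0) {
      message(sprintf("  frame %d/%d: %d tracked detections", f,
                      source$n_frames, nrow(obj)))
    }
  }
  det <- dplyr::bind_rows(detections)
  tracks <- link_frames(det, cfg$tracking$gate_um, cfg$tracking$memory_frames)
  speeds <- windowed_speed(tracks, cfg$tracking$window_frames,
                           cfg$tracking$interval_min)
  series <- if (nrow(speeds)) {
    median_speed_series(speeds, cfg$tracking$smooth_frames)
  } else {
    tibble::tibble(frame = numeric(0), median_speed = numeric(0),
                   n_cells = integer(0), smoothed = numeric(0))
  }
  list(z_eff = z_eff, detections = det, tracks = tracks, speeds = speeds,
       series = series, class_counts = dplyr::bind_rows(counts))
}

#' Run the full multi-channel pipeline
#'
#' Processes each channel independently through the complete chain --
#' magnification rescaling, (optional) inter-height registration, per-height
#' autofocus on the first burst, multi-height phase retrieval with the
#' positive absorption constraint, fixed-threshold segmentation with area
#' classification, optimal-assignment tracking of single cells, windowed
#' speeds and per-frame medians -- then compares every channel's median
#' speed against the control (first) channel.
#'
#' @param sources Named list of `burst_source` objects (first = control).
#' @param cfg An `experiment_config` ([default_config()]).
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @param frame_range Optional frame range for the ratio computation
#'   (default: all frames where both channels have defined medians).
#' @param verbose Print per-channel progress.
#' @return A `holotrack_report`: per-channel speed `series` (long tibble),
#'   pairwise `ratios` vs control, per-class object `counts`, focus
#'   distances, tracks, and the configuration used.
#' @export
run_pipeline <- function(sources, cfg = default_config(), out_dir = NULL,
                         frame_range = NULL, verbose = FALSE) {
  stopifnot(length(sources) >= 1)
  if (is.null(names(sources)) || any(names(sources) == "")) {
    names(sources) <- vapply(sources, function(s) s$label, character(1))
  }
  geometry <- config_geometry(cfg)
  results <- list()
  for (label in names(sources)) {
    if (verbose) message("channel ", label)
    results[[label]] <- run_channel(sources[[label]], cfg, geometry, verbose)
  }
  series <- dplyr::bind_rows(
    lapply(names(results), function(l) {
      dplyr::mutate(tibble::as_tibble(results[[l]]$series), channel = l,
                    .before = 1)
    }))
  control <- names(results)[1]
  ratios <- dplyr::bind_rows(lapply(names(results)[-1], function(l) {
    r <- tryCatch(
      speed_ratio(results[[l]]$series, results[[control]]$series, frame_range),
      error = function(e) NA_real_)
    tibble::tibble(channel = l, control = control, speed_ratio = r)
  }))
  counts <- dplyr::bind_rows(lapply(names(results), function(l) {
    dplyr::mutate(results[[l]]$class_counts, channel = l, .before = 1)
  }))
  report <- structure(list(
    series = series, ratios = ratios, counts = counts,
    focus_mm = lapply(results, function(r) r$z_eff),
    tracks = lapply(results, function(r) r$tracks),
    config = cfg
  ), class = "holotrack_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(series, file.path(out_dir, "median_speeds.csv"),
                     row.names = FALSE)
    utils::write.csv(counts, file.path(out_dir, "class_counts.csv"),
                     row.names = FALSE)
    for (l in names(results)) {
      utils::write.csv(results[[l]]$tracks,
                       file.path(out_dir, paste0("tracks_", l, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(ratios = ratios,
           focus_mm = report$focus_mm,
           config = unclass(cfg)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  report
}

#' @export
print.holotrack_report <- function(x, ...) {
  cat("<holotrack_report>\n channels:",
      paste(unique(x$series$channel), collapse = ", "), "\n")
  if (nrow(x$ratios)) {
    for (i in seq_len(nrow(x$ratios))) {
      cat(sprintf(" median-speed ratio %s / %s = %.3f\n",
                  x$ratios$channel[i], x$ratios$control[i],
                  x$ratios$speed_ratio[i]))
    }
  }
  invisible(x)
}

#' Tidy a pipeline report into its speed series
#'
#' @param x A `holotrack_report`.
#' @param ... Unused.
#' @return The long per-channel speed series tibble.
#' @export
tidy.holotrack_report <- function(x, ...) x$series

#' One-row summary of a pipeline report
#'
#' @param x A `holotrack_report`.
#' @param ... Unused.
#' @return Tibble with channel count, frame count and the max ratio.
#' @export
glance.holotrack_report <- function(x, ...) {
  tibble::tibble(
    n_channels = length(unique(x$series$channel)),
    n_frames_defined = length(unique(x$series$frame)),
    max_speed_ratio = if (nrow(x$ratios)) max(x$ratios$speed_ratio) else NA_real_
  )
}
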