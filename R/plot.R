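# ggplot2 presentation of result objects.

#' Plot a per-frame median speed series
#'
#' Dot plot of the per-frame median speed of individual cells with the
#' smoothed curve overlaid, the standard presentation of culture-level
#' migration speed over time.
#'
#' @param object A `speed_series` tibble ([median_speed_series()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.speed_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frame, y = .data$median_speed)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.8,
                       na.rm = TRUE) +
    ggplot2::labs(x = "frame", y = "median speed (µm/min)") +
    ggplot2::theme_minimal()
}

#' Plot a multi-channel pipeline report
#'
#' One dot series plus smoothed curve per channel.
#'
#' @param object A `holotrack_report` ([run_pipeline()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.holotrack_report <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(x = .data$frame, y = .data$median_speed,
                               colour = .data$channel)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), linewidth = 0.9,
                       na.rm = TRUE) +
    ggplot2::labs(x = "frame", y = "median speed (µm/min)",
                  colour = "channel") +
    ggplot2::theme_minimal()
}

#' Display a reconstructed phase map
#'
#' @param object A `phase_reconstruction`.
#' @param what `"phase"` or `"amplitude"`.
#' @param ... Unused.
#' @return A ggplot raster image in physical coordinates (um).
#' @export
autoplot.phase_reconstruction <- function(object,
                                          what = c("phase", "amplitude"),
                                          ...) {
  what <- match.arg(what)
  m <- object[[what]]
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$value <- as.vector(t(m))[(df$y - 1) * ncol(m) + df$x]
  df$x_um <- (df$x - 0.5) * object$pitch_um
  df$y_um <- (df$y - 0.5) * object$pitch_um
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = if (what == "phase") "rad" else "") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Display a segmented frame
#'
#' Object centroids coloured by size class over the label map footprint.
#'
#' @param object A `segmented_frame`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.segmented_frame <- function(object, ...) {
  ggplot2::ggplot(object$objects,
                  ggplot2::aes(.data$x_um, .data$y_um,
                               colour = .data$size_class,
                               size = .data$area_um2)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  colour = "class", size = "area (µm²)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
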