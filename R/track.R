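# Frame-to-frame linking by globally optimal assignment, windowed migration
# speeds, per-frame median speed series.

# Jonker-Volgenant shortest-augmenting-path solver for the square linear
# assignment problem (minimise total cost). Deterministic: ties resolve to
# the lowest column index. Costs must be finite; use a large sentinel for
# forbidden pairs.
lap_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 0) return(integer(0))
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1)    # column potentials; n+1 is the virtual start column
  p <- integer(n + 1)    # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)  # predecessor column on the alternating path
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- cost[i0, ] - u[i0] - v[cols]
      upd <- !used[cols] & cur < minv
      minv[upd] <- cur[upd]
      way[upd] <- j0
      free <- which(!used[cols])
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedc <- which(used)
      rows <- p[usedc]
      u[rows[rows > 0]] <- u[rows[rows > 0]] + delta
      v[usedc] <- v[usedc] - delta
      minv[!used[cols]] <- minv[!used[cols]] - delta
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  assignment <- integer(n)
  assignment[p[cols]] <- cols
  assignment
}

# Link one frame: returns an integer vector `match` of length n_tracks
# (detection index or NA) plus the detection indices that start new tracks.
# Implemented as the standard augmented LAP: an (n+m) square matrix with the
# gated distance block, diagonal "track ends" and "track starts" blocks at
# the gate cost, and a complementary block of zeros.
match_frame <- function(track_xy, det_xy, gate_um) {
  n <- nrow(track_xy); m <- nrow(det_xy)
  if (n == 0 || m == 0) {
    return(list(match = rep(NA_integer_, n), new = seq_len(m)))
  }
  d <- sqrt(outer(track_xy[, 1], det_xy[, 1], `-`)^2 +
              outer(track_xy[, 2], det_xy[, 2], `-`)^2)
  big <- 2 * gate_um * (n + m) + 1e6
  link <- ifelse(d <= gate_um, d, big)
  topright <- matrix(big, n, n); diag(topright) <- gate_um
  botleft <- matrix(big, m, m); diag(botleft) <- gate_um
  botright <- t(ifelse(d <= gate_um, 0, big))
  cost <- rbind(cbind(link, topright), cbind(botleft, botright))
  a <- lap_solve(cost)
  match <- rep(NA_integer_, n)
  ai <- a[seq_len(n)]
  hit <- which(ai <= m)
  hit <- hit[link[cbind(hit, ai[hit])] < big]
  match[hit] <- ai[hit]
  list(match = match, new = setdiff(seq_len(m), match))
}

#' Link per-frame detections into cell tracks
#'
#' Builds trajectories by solving, for each consecutive frame pair, a
#' globally optimal (minimum total distance) one-to-one assignment between
#' open track heads and new detections. Links longer than `gate_um` are
#' forbidden; unmatched detections open new tracks; tracks unmatched for more
#' than `memory_frames` consecutive frames are closed (they coast at their
#' last position while within memory). Detection order within a frame does
#' not affect the result.
#'
#' @param detections Tibble/data.frame with columns `frame`, `x_um`, `y_um`
#'   (one row per detection; additional columns are ignored).
#' @param gate_um Maximum allowed frame-to-frame displacement (um),
#'   default 20: twice the protocol's fastest plausible motion of
#'   1 px/min x 5 min at 2 um pixels.
#' @param memory_frames Number of consecutive missed frames a track survives,
#'   default 3.
#' @return A `cell_tracks` tibble: `track_id`, `frame`, `x_um`, `y_um`,
#'   ordered by track then frame.
#' @export
link_frames <- function(detections, gate_um = 20, memory_frames = 3) {
  stopifnot(gate_um > 0, memory_frames >= 0)
  detections <- tibble::as_tibble(detections)
  if (nrow(detections) == 0) {
    out <- tibble::tibble(track_id = integer(0), frame = integer(0),
                          x_um = numeric(0), y_um = numeric(0))
    class(out) <- c("cell_tracks", class(out))
    return(out)
  }
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  by_frame <- split(detections[, c("x_um", "y_um")], detections$frame)
  active <- list()   # each: id, x, y, last_frame, missed
  next_id <- 1L
  rows <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det <- as.matrix(by_frame[[as.character(f)]])
    # age out tracks beyond memory
    if (length(active)) {
      keep <- vapply(active, function(tr) f - tr$last_frame <= memory_frames + 1,
                     logical(1))
      active <- active[keep]
    }
    if (length(active)) {
      heads <- do.call(rbind, lapply(active, function(tr) c(tr$x, tr$y)))
      mm <- match_frame(heads, det, gate_um)
    } else {
      mm <- list(match = integer(0), new = seq_len(nrow(det)))
    }
    for (ti in seq_along(active)) {
      j <- mm$match[ti]
      if (!is.na(j)) {
        active[[ti]]$x <- det[j, 1]; active[[ti]]$y <- det[j, 2]
        active[[ti]]$last_frame <- f
      }
    }
    new_rows <- list()
    k <- 0L
    for (ti in seq_along(active)) {
      if (active[[ti]]$last_frame == f) {
        k <- k + 1L
        new_rows[[k]] <- c(active[[ti]]$id, f, active[[ti]]$x, active[[ti]]$y)
      }
    }
    for (j in mm$new) {
      active[[length(active) + 1L]] <- list(id = next_id, x = det[j, 1],
                                            y = det[j, 2], last_frame = f)
      k <- k + 1L
      new_rows[[k]] <- c(next_id, f, det[j, 1], det[j, 2])
      next_id <- next_id + 1L
    }
    rows[[fi]] <- do.call(rbind, new_rows)
  }
  m <- do.call(rbind, rows)
  out <- tibble::tibble(track_id = as.integer(m[, 1]), frame = m[, 2],
                        x_um = m[, 3], y_um = m[, 4])
  out <- dplyr::arrange(out, .data$track_id, .data$frame)
  class(out) <- c("cell_tracks", class(out))
  out
}

#' Windowed migration speed along tracks
#'
#' The speed of a cell at frame `n` is the distance it travelled over its
#' last `window_frames` steps divided by the time those frames took
#' (protocol: 50 frames of 5 min = 250 min). "Distance travelled" is by
#' default the summed step path length; `method = "net"` uses the net
#' displacement instead. Frames with fewer than `window_frames` preceding
#' points carry no speed.
#'
#' @param tracks A `cell_tracks` tibble (or any tibble with `track_id`,
#'   `frame`, `x_um`, `y_um`).
#' @param window_frames Window length W in frames (>= 2), default 50.
#' @param interval_min Frame interval in minutes, default 5.
#' @param method `"path"` (default) or `"net"`.
#' @return Tibble `track_id`, `frame`, `speed_um_per_min` (only rows where
#'   the speed is defined).
#' @export
windowed_speed <- function(tracks, window_frames = 50, interval_min = 5,
                           method = c("path", "net")) {
  stopifnot(window_frames >= 2, interval_min > 0)
  method <- match.arg(method)
  tracks <- tibble::as_tibble(tracks)
  one <- function(df) {
    np <- nrow(df)
    if (np <= window_frames) {
      return(tibble::tibble(frame = numeric(0), speed_um_per_min = numeric(0)))
    }
    i <- (window_frames + 1L):np
    if (method == "path") {
      step <- sqrt(diff(df$x_um)^2 + diff(df$y_um)^2)
      cs <- cumsum(c(0, step))
      dist <- cs[i] - cs[i - window_frames]
    } else {
      dist <- sqrt((df$x_um[i] - df$x_um[i - window_frames])^2 +
                     (df$y_um[i] - df$y_um[i - window_frames])^2)
    }
    tibble::tibble(frame = df$frame[i],
                   speed_um_per_min = dist / (window_frames * interval_min))
  }
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Per-frame median speed series
#'
#' The per-frame median of the individual-cell windowed speeds: one value per
#' frame where at least one track has a defined speed. An optional centred
#' moving average (presentation only) is stored alongside the raw medians.
#'
#' @param speeds Output of [windowed_speed()].
#' @param smooth_frames Width of the centred moving average (0 disables),
#'   default 20.
#' @return A `speed_series` tibble: `frame`, `median_speed`, `n_cells`,
#'   `smoothed`.
#' @export
median_speed_series <- function(speeds, smooth_frames = 20) {
  speeds <- tibble::as_tibble(speeds)
  out <- speeds |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(median_speed = stats::median(.data$speed_um_per_min),
                     n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$frame)
  if (smooth_frames > 1 && nrow(out) >= smooth_frames) {
    sm <- stats::filter(out$median_speed,
                        rep(1 / smooth_frames, smooth_frames), sides = 2)
    out$smoothed <- as.numeric(sm)
  } else {
    out$smoothed <- out$median_speed
  }
  class(out) <- c("speed_series", class(out))
  out
}

#' Median-speed ratio between two channels
#'
#' Compares two speed series over the frames where both have a defined
#' median: the ratio of the pooled medians of the per-frame median speeds.
#'
#' @param series_a,series_b `speed_series` tibbles (numerator, denominator).
#' @param frame_range Optional length-2 frame range to restrict to.
#' @return Single ratio (numerator over denominator).
#' @export
speed_ratio <- function(series_a, series_b, frame_range = NULL) {
  common <- intersect(series_a$frame, series_b$frame)
  if (!is.null(frame_range)) {
    common <- common[common >= frame_range[1] & common <= frame_range[2]]
  }
  if (length(common) == 0) stop("no common frames with defined medians")
  a <- series_a$median_speed[match(common, series_a$frame)]
  b <- series_b$median_speed[match(common, series_b$frame)]
  stats::median(a) / stats::median(b)
}

#' Tidy cell tracks
#'
#' @param x A `cell_tracks` tibble.
#' @param ... Unused.
#' @return Plain tibble of the track points.
#' @export
tidy.cell_tracks <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Track-level summary
#'
#' @param x A `cell_tracks` tibble.
#' @param ... Unused.
#' @return One row per track: birth/death frame, number of points, total path
#'   length (um).
#' @export
glance.cell_tracks <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      birth_frame = min(.data$frame),
      death_frame = max(.data$frame),
      n_points = dplyr::n(),
      path_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
      .groups = "drop")
}
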