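test_that("the assignment solver matches brute-force enumeration", {
  brute <- function(cost) {
    n <- nrow(cost)
    best <- Inf
    rec <- function(free, acc) {
      if (!length(free)) {
        best <<- min(best, sum(cost[cbind(seq_len(n), acc)]))
        return(invisible())
      }
      for (x in free) rec(setdiff(free, x), c(acc, x))
    }
    rec(seq_len(n), integer(0))
    best
  }
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n)
    a <- holotrack:::lap_solve(cost)
    expect_equal(sort(a), seq_len(n))        # a permutation
    expect_equal(sum(cost[cbind(seq_len(n), a)]), brute(cost),
                 tolerance = 1e-12)
  }
})

test_that("simple linking cases produce the expected tracks", {
  # one stationary detection over 10 frames -> one track of length 10
  det <- tibble::tibble(frame = 1:10, x_um = 50, y_um = 50)
  tr <- link_frames(det, gate_um = 10)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)

  # two detections always far apart -> two tracks, no switches
  det2 <- dplyr::bind_rows(
    tibble::tibble(frame = 1:10, x_um = 10, y_um = 10),
    tibble::tibble(frame = 1:10, x_um = 90, y_um = 90))
  tr2 <- link_frames(det2, gate_um = 10)
  expect_equal(length(unique(tr2$track_id)), 2)
  expect_true(all(table(tr2$track_id) == 10))
  per_track_x <- tapply(tr2$x_um, tr2$track_id, function(x) length(unique(x)))
  expect_true(all(per_track_x == 1))

  # empty input is not an error
  expect_equal(nrow(link_frames(tibble::tibble(frame = numeric(0),
                                               x_um = numeric(0),
                                               y_um = numeric(0)))), 0)
})

test_that("linking respects the gate and detection conservation", {
  scene <- generate_scene(n_cells = 30, speed_um_per_min = 0.4,
                          n_frames = 40, fov_um = 400, seed = 6)
  det <- scene$positions
  tr <- link_frames(det, gate_um = 8, memory_frames = 3)
  steps <- tr |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(max_step = if (dplyr::n() > 1)
      max(sqrt(diff(x_um)^2 + diff(y_um)^2) / pmax(diff(frame), 1)) else 0)
  expect_true(all(steps$max_step <= 8 + 1e-9))
  # each detection used at most once per frame
  expect_false(any(duplicated(tr[, c("track_id", "frame")])))
  expect_lte(nrow(tr), nrow(det))
})

test_that("shuffling detection order does not change the track set", {
  scene <- generate_scene(n_cells = 15, speed_um_per_min = 0.4,
                          n_frames = 15, fov_um = 250, seed = 13)
  det <- scene$positions
  set.seed(99)
  shuffled <- det[sample(nrow(det)), ]
  norm <- function(tr) {
    tr |>
      dplyr::arrange(.data$frame, .data$x_um, .data$y_um) |>
      dplyr::select("frame", "x_um", "y_um") |>
      as.data.frame()
  }
  t1 <- link_frames(det, gate_um = 10)
  t2 <- link_frames(shuffled, gate_um = 10)
  expect_equal(norm(t1), norm(t2))
  expect_equal(length(unique(t1$track_id)), length(unique(t2$track_id)))
})

test_that("ground-truth correspondences are recovered at high accuracy", {
  scene <- generate_scene(n_cells = 50, speed_um_per_min = 0.3,
                          n_frames = 100, fov_um = 500, seed = 5)
  det <- scene$positions
  tr <- link_frames(det, gate_um = 10, memory_frames = 3)
  expect_equal(length(unique(tr$track_id)), 50)
  joined <- dplyr::inner_join(tr, det, by = c("frame", "x_um", "y_um"))
  tab <- table(joined$track_id, joined$cell_id)
  expect_gte(sum(apply(tab, 1, max)) / nrow(joined), 0.95)
})

test_that("windowed speed follows its defining arithmetic", {
  # straight line at 1 um per frame, 5 min interval, W = 50 -> 0.2 um/min
  tk <- tibble::tibble(track_id = 1L, frame = 1:60, x_um = as.numeric(1:60),
                       y_um = 0)
  ws <- windowed_speed(tk, window_frames = 50, interval_min = 5)
  expect_equal(nrow(ws), 10)
  expect_true(all(abs(ws$speed_um_per_min - 0.2) < 1e-12))
  expect_equal(ws$frame, 51:60)

  # stationary -> zero
  still <- tibble::tibble(track_id = 1L, frame = 1:60, x_um = 5, y_um = 5)
  expect_true(all(windowed_speed(still, 50, 5)$speed_um_per_min == 0))

  # a track shorter than the window has no defined speed
  short <- tibble::tibble(track_id = 1L, frame = 1:30, x_um = 1:30, y_um = 0)
  expect_equal(nrow(windowed_speed(short, 50, 5)), 0)

  # net displacement halves the speed of a perfect zig-zag
  zig <- tibble::tibble(track_id = 1L, frame = 1:60,
                        x_um = rep(c(0, 1), 30), y_um = 0)
  path <- windowed_speed(zig, 50, 5)$speed_um_per_min
  net <- windowed_speed(zig, 50, 5, method = "net")$speed_um_per_min
  expect_true(all(path > 10 * net))
})

test_that("the median series pools cells per frame", {
  tracks <- dplyr::bind_rows(lapply(c(1, 2, 9), function(v) {
    tibble::tibble(track_id = v, frame = 1:60, x_um = (1:60) * v / 5,
                   y_um = 0)
  }))
  sp <- windowed_speed(tracks, 50, 5)
  ms <- median_speed_series(sp, smooth_frames = 0)
  # per-frame step v/5 um at 5 min -> speeds v/25; median of (1,2,9)/25
  expect_true(all(abs(ms$median_speed - 2 / 25) < 1e-9))
  expect_true(all(ms$n_cells == 3))

  # single track: series equals that track's speed
  one <- windowed_speed(tracks[tracks$track_id == 1, ], 50, 5)
  ms1 <- median_speed_series(one, smooth_frames = 0)
  expect_equal(ms1$median_speed, one$speed_um_per_min)
})

test_that("windowed speeds recover simulated culture speeds and ratios", {
  run <- function(speed, seed) {
    scene <- generate_scene(n_cells = 40, speed_um_per_min = speed,
                            n_frames = 120, fov_um = 600, seed = seed)
    sp <- windowed_speed(link_frames(scene$positions, gate_um = 10),
                         window_frames = 50, interval_min = 5)
    median_speed_series(sp, smooth_frames = 0)
  }
  slow <- run(0.2, 31)
  fast <- run(0.5, 32)
  expect_equal(stats::median(slow$median_speed), 0.2, tolerance = 0.1)
  expect_equal(stats::median(fast$median_speed), 0.5, tolerance = 0.1)
  expect_equal(speed_ratio(fast, slow), 2.5, tolerance = 0.15 * 2.5)
  expect_equal(speed_ratio(slow, slow), 1)
})
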