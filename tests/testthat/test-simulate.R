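test_that("scene generation honours trivial limits and exact step lengths", {
  empty <- generate_scene(0, n_frames = 5)
  expect_equal(nrow(empty$positions), 0)

  still <- generate_scene(5, speed_um_per_min = 0, n_frames = 8, seed = 2)
  spread <- still$positions |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(dx = diff(range(.data$x_um)),
                     dy = diff(range(.data$y_um)))
  expect_true(all(spread$dx == 0 & spread$dy == 0))

  # persistent random walk: every step has exactly speed x interval length
  # (wall reflections fold the path, so exactness is asserted away from the
  # reflecting margin)
  scene <- generate_scene(50, speed_um_per_min = 0.5, n_frames = 200,
                          fov_um = 600, seed = 14)
  steps <- scene$positions |>
    dplyr::arrange(.data$cell_id, .data$frame) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::reframe(
      step = sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2),
      # start point far enough from the reflecting walls (at 25 / 575 um)
      # that a 2.5 um step cannot reach them
      interior = utils::head(
        pmin(.data$x_um - 25, 575 - .data$x_um,
             .data$y_um - 25, 575 - .data$y_um), -1) > 2.5)
  expect_lt(max(abs(steps$step[steps$interior] - 2.5)), 1e-9)
  expect_equal(mean(steps$step), 2.5, tolerance = 0.01)

  # windowed path-length speed over those tracks is the nominal speed
  sp <- windowed_speed(link_frames(scene$positions, gate_um = 10),
                       window_frames = 50, interval_min = 5)
  expect_equal(mean(sp$speed_um_per_min), 0.5, tolerance = 0.01)

  expect_error(generate_scene(5, speed_um_per_min = -1), "speed")
  expect_error(generate_scene(-1), "n_cells")
})

test_that("cells stay inside the reflecting margin", {
  scene <- generate_scene(30, speed_um_per_min = 2, n_frames = 300,
                          fov_um = 200, margin_um = 25, seed = 4)
  expect_true(all(scene$positions$x_um >= 25 - 1e-9))
  expect_true(all(scene$positions$x_um <= 175 + 1e-9))
  expect_true(all(scene$positions$y_um >= 25 - 1e-9))
  expect_true(all(scene$positions$y_um <= 175 + 1e-9))
})

test_that("scenes and rendered bursts are deterministic under a seed", {
  s1 <- generate_scene(10, n_frames = 6, seed = 42)
  s2 <- generate_scene(10, n_frames = 6, seed = 42)
  expect_identical(s1$positions, s2$positions)
  s3 <- generate_scene(10, n_frames = 6, seed = 43)
  expect_false(identical(s1$positions, s3$positions))

  geom <- small_geometry()
  b1 <- render_burst(s1, 1, geom, seed = 7)
  b2 <- render_burst(s1, 1, geom, seed = 7)
  expect_identical(b1$images, b2$images)
})

test_that("the forward model is PAC-consistent and energy-sane", {
  scene <- generate_scene(6, n_frames = 1, fov_um = 150, seed = 5)
  tr <- scene_transmittance(scene, 1, 1, 160)
  expect_true(all(Mod(tr$values) <= 1 + 1e-12))
  expect_true(all(tr$absorbance >= 0))

  geom <- small_geometry()
  burst <- render_burst(scene, 1, geom, photons = Inf, read_noise = 0,
                        seed = 1)
  expect_equal(length(burst$images), 5)
  mean_level <- mean(burst$images[[1]]) / 20000
  expect_equal(mean_level, 1, tolerance = 0.05)

  # empty scene: only noise around the background level
  empty <- generate_scene(0, n_frames = 1, fov_um = 150)
  bempty <- render_burst(empty, 1, geom, photons = Inf, read_noise = 0,
                         seed = 1)
  expect_lt(stats::sd(bempty$images[[3]]) / mean(bempty$images[[3]]), 1e-3)
})

test_that("fringe patterns widen with propagation distance", {
  # single on-axis cell: Fresnel scaling predicts the ring pattern of
  # height k to be the reference pattern radially stretched by
  # sqrt(z_eff_k / z_eff_1) (times the extra geometric magnification).
  # The stretch is estimated by correlating radial profiles.
  geom <- small_geometry()
  scene <- generate_scene(1, speed_um_per_min = 0, n_frames = 1,
                          fov_um = 400, seed = 1)
  scene$positions$x_um <- 200
  scene$positions$y_um <- 200
  burst <- render_burst(scene, 1, geom, photons = Inf, read_noise = 0,
                        seed = 1)
  profile <- lapply(burst$images, function(img) {
    n <- nrow(img)
    ctr <- (n + 1) / 2
    xs <- matrix(rep(seq_len(n), each = n), n)
    r <- round(sqrt((xs - ctr)^2 + (t(xs) - ctr)^2))
    as.numeric(tapply(as.vector(img), as.vector(r), mean))[1:160] - 20000
  })
  stretch <- vapply(profile, function(p) {
    s_grid <- seq(0.9, 1.4, by = 0.005)
    cors <- vapply(s_grid, function(s) {
      ref <- stats::approx(seq_along(profile[[1]]), profile[[1]],
                           xout = seq_along(p) / s)$y
      ok <- !is.na(ref)
      stats::cor(ref[ok], p[ok])
    }, numeric(1))
    s_grid[which.max(cors)]
  }, numeric(1))
  gt <- geometry_table(geom)
  predicted <- sqrt(gt$z_eff_mm / gt$z_eff_mm[1]) *
    gt$magnification / gt$magnification[1]
  expect_equal(stretch[1], 1)
  expect_gt(stats::cor(stretch, predicted), 0.8)
  expect_gt(stretch[5], stretch[1] + 0.05)
  expect_true(all(stretch >= 0.99))
})

test_that("timestamp arithmetic matches the acquisition cadence", {
  expect_equal(n_timestamps(68.5, 5), 823L)
  expect_equal(n_timestamps(0, 5), 1L)
})

test_that("experiment trees are written deterministically", {
  channels <- tibble::tibble(label = c("A", "B"),
                             speed_um_per_min = c(0.2, 0.5),
                             n_cells = c(3, 3))
  geom <- small_geometry()
  d1 <- file.path(tempdir(), "exp1"); d2 <- file.path(tempdir(), "exp2")
  unlink(c(d1, d2), recursive = TRUE)
  make_experiment(d1, channels, n_frames = 2, geometry = geom,
                  fov_um = 100, seed = 9)
  make_experiment(d2, channels, n_frames = 2, geometry = geom,
                  fov_um = 100, seed = 9)
  expect_true(file.exists(file.path(d1, "A", "t0001_h1.tif")))
  expect_true(file.exists(file.path(d1, "ground_truth", "positions.csv")))
  expect_identical(readLines(file.path(d1, "ground_truth", "positions.csv")),
                   readLines(file.path(d2, "ground_truth", "positions.csv")))
  expect_identical(
    tools::md5sum(file.path(d1, "B", "t0002_h5.tif"))[[1]],
    tools::md5sum(file.path(d2, "B", "t0002_h5.tif"))[[1]])
  # refuses to clobber without force
  expect_error(make_experiment(d1, channels, n_frames = 1, geometry = geom,
                               fov_um = 100, seed = 9), "force")
  # bursts read back identical to what was rendered
  burst <- read_burst_dir(file.path(d1, "A"), 1, geom)
  scene <- generate_scene(3, speed_um_per_min = 0.2, n_frames = 2,
                          fov_um = 100, seed = 9 * 1000L + 1L)
  direct <- render_burst(scene, 1, geom, seed = 9 * 1000L + 100000L + 1L)
  expect_equal(burst$images, direct$images)
  unlink(c(d1, d2), recursive = TRUE)
})
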