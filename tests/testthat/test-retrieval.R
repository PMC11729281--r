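test_that("hologram normalization has unit background and scale invariance", {
  uniform <- matrix(7, 32, 32)
  expect_equal(normalize_hologram(uniform), matrix(1, 32, 32))
  img <- matrix(runif(32^2, 0.5, 1.5), 32)
  expect_equal(normalize_hologram(img, sigma = 0),
               normalize_hologram(img * 13, sigma = 0))
  expect_error(normalize_hologram(matrix(0, 8, 8)), "all-zero")
  expect_error(normalize_hologram(matrix(-1, 8, 8)), "non-negative")
})

test_that("normalization flattens a smooth illumination gradient", {
  # empty scene: the hologram is pure illumination, so any residual
  # structure after normalization is the background estimator's error
  geom <- small_geometry()
  empty <- generate_scene(0, n_frames = 1, fov_um = 150)
  raw <- render_burst(empty, 1, geom, photons = Inf, read_noise = 0,
                      seed = 1)$images[[1]]
  xs <- matrix(rep(seq_len(ncol(raw)), each = nrow(raw)), nrow(raw))
  gradient <- 1 + 0.4 * xs / ncol(raw)
  amp <- normalize_hologram(raw * gradient)
  expect_lt(stats::sd(amp), 0.02)
  expect_equal(mean(amp), 1, tolerance = 0.01)
})

test_that("the positive absorption constraint caps amplitude and is idempotent", {
  set.seed(4)
  v <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8)
  once <- apply_pac(v)
  expect_true(all(Mod(once) <= 1 + 1e-6))
  expect_identical(apply_pac(once), once)
  # phase untouched
  expect_equal(Arg(once), Arg(v), tolerance = 1e-12)
  # sub-unit amplitudes pass through
  small <- v / (2 * max(Mod(v)))
  expect_identical(apply_pac(small), small)
})

test_that("a uniform burst reconstructs to flat phase and unit amplitude", {
  geom <- small_geometry()
  gt <- geometry_table(geom)
  imgs <- replicate(5, matrix(1000, 64, 64), simplify = FALSE)
  burst <- hologram_burst(imgs, geom$z2_mm)
  burst <- rescale_burst_to_reference(burst, geom)
  rec <- gs_pac_reconstruct(burst, gt$z_eff_mm, n_iter = 3, pad = 0)
  expect_lt(stats::var(as.vector(rec$phase)), 1e-10)
  expect_equal(max(abs(rec$amplitude - 1)), 0, tolerance = 1e-6)

  flat <- backpropagate_single(matrix(1, 64, 64), 13.5, 1.8)
  expect_lt(stats::var(as.vector(flat$phase)), 1e-12)
})

test_that("retrieval rejects invalid inputs", {
  geom <- small_geometry()
  gt <- geometry_table(geom)
  imgs <- replicate(5, matrix(1, 16, 16), simplify = FALSE)
  burst <- rescale_burst_to_reference(hologram_burst(imgs, geom$z2_mm), geom)
  expect_error(gs_pac_reconstruct(burst, gt$z_eff_mm, n_iter = 0), "n_iter")
  expect_error(gs_pac_reconstruct(burst, rev(gt$z_eff_mm)), "increasing")
  expect_error(gs_pac_reconstruct(burst, gt$z_eff_mm[1:3]), "one focus")
  one <- rescale_burst_to_reference(
    hologram_burst(imgs[1], geom$z2_mm[1]),
    acquisition_geometry(z2_mm = 15, camera_pitch_um = 1))
  expect_error(gs_pac_reconstruct(one, 13.5), "K >= 2")
})

test_that("multi-height retrieval beats the single-height baseline", {
  fx <- separated_culture()
  bg <- fx$truth$phase < 0.01
  err_gs <- sqrt(mean((fx$recon$phase - fx$truth$phase)^2))
  err_base <- sqrt(mean((fx$baseline$phase - fx$truth$phase)^2))
  expect_lt(err_gs, 0.1)
  expect_lt(err_gs, err_base)
  # twin-image suppression: quieter object-free background
  expect_lt(stats::var(fx$recon$phase[bg]),
            stats::var(fx$baseline$phase[bg]) / 2)
  # PAC enforced on the final iterate
  expect_true(all(fx$recon$amplitude <= 1 + 1e-6))
})

test_that("the data-fidelity residual is non-increasing across sweeps", {
  fx <- separated_culture()
  res <- fx$recon$residuals
  expect_gt(length(res), 1)
  expect_true(all(diff(res) <= 1e-3 * res[-length(res)]))
})

test_that("degenerate two-plane retrieval reduces to constrained backprop", {
  fx <- separated_culture()
  amp <- normalize_hologram(fx$rescaled$images[[1]])
  z <- fx$gt$z_eff_mm[1]
  burst <- hologram_burst(list(fx$rescaled$images[[1]],
                               fx$rescaled$images[[1]]),
                          c(15, 15 + 1e-9))
  burst$rescaled <- TRUE
  burst$object_pitch_um <- fx$gt$object_pitch_um[1]
  rec <- gs_pac_reconstruct(burst, c(z, z + 1e-9), n_iter = 1, pad = 0)
  base <- backpropagate_single(amp, z, fx$gt$object_pitch_um[1], pad = 0)
  expect_phase_close(rec$phase, base$phase, 1e-4)
  expect_equal(rec$amplitude, pmin(base$amplitude, 1), tolerance = 1e-6)
})

test_that("defocused reconstruction scores a worse focus metric", {
  fx <- separated_culture()
  amp <- normalize_hologram(fx$rescaled$images[[1]])
  p1 <- fx$gt$object_pitch_um[1]
  in_focus <- backpropagate_single(amp, fx$gt$z_eff_mm[1], p1, pad = 0)
  defocus <- backpropagate_single(amp, fx$gt$z_eff_mm[1] + 5, p1, pad = 0)
  m_in <- focus_metric(in_focus$amplitude * exp(1i * in_focus$phase))
  m_out <- focus_metric(defocus$amplitude * exp(1i * defocus$phase))
  expect_gt(m_in, m_out)
})

test_that("phase error degrades with increasing shot noise", {
  geom <- small_geometry()
  gt <- geometry_table(geom)
  scene <- generate_scene(n_cells = 4, speed_um_per_min = 0, n_frames = 1,
                          fov_um = 120, seed = 11)
  truth <- NULL
  err_at <- function(photons, seed) {
    burst <- render_burst(scene, 1, geom, photons = photons, read_noise = 0,
                          seed = seed)
    rb <- rescale_burst_to_reference(burst, geom)
    rec <- gs_pac_reconstruct(rb, gt$z_eff_mm, n_iter = 8, pad = 0)
    if (is.null(truth)) {
      truth <<- scene_transmittance(scene, 1, gt$object_pitch_um[1],
                                    nrow(rb$images[[1]]))$phase
    }
    sqrt(mean((rec$phase - truth)^2))
  }
  seeds <- 1:5
  err_clean <- mean(vapply(seeds, function(s) err_at(Inf, s), numeric(1)))
  err_mid <- mean(vapply(seeds, function(s) err_at(5000, s), numeric(1)))
  err_high <- mean(vapply(seeds, function(s) err_at(300, s), numeric(1)))
  expect_lte(err_clean, err_mid)
  expect_lte(err_mid, err_high)
})
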