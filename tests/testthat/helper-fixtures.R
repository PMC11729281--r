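# Shared fixtures. Heavy simulated objects are built once per test run and
# cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small acquisition: protocol distances, 1 um camera pitch so single cells
# span enough pixels on a compact grid.
small_geometry <- function() acquisition_geometry(camera_pitch_um = 1.0)

# Static 9-cell culture on a jittered grid (guaranteed separation), rendered
# noiselessly and reconstructed; used by retrieval and segmentation tests.
separated_culture <- function() {
  fixture("separated_culture", function() {
    geom <- small_geometry()
    gt <- geometry_table(geom)
    scene <- generate_scene(n_cells = 9, speed_um_per_min = 0, n_frames = 1,
                            fov_um = 250, seed = 3)
    # jittered grid: guaranteed separation without the spatial periodicity
    # that would let the hologram self-image at Talbot-like distances
    gridpos <- expand.grid(x = c(60, 125, 190), y = c(60, 125, 190))
    scene$positions$x_um <- gridpos$x + c(4, -6, 2, 7, -3, 5, -7, 1, -2)
    scene$positions$y_um <- gridpos$y + c(-5, 3, 6, -2, 7, -4, 2, -6, 4)
    burst <- render_burst(scene, 1, geom, photons = Inf, read_noise = 0,
                          seed = 1)
    rescaled <- rescale_burst_to_reference(burst, geom)
    recon <- gs_pac_reconstruct(rescaled, gt$z_eff_mm, n_iter = 30, pad = 0)
    baseline <- backpropagate_single(
      normalize_hologram(rescaled$images[[1]]), gt$z_eff_mm[1],
      gt$object_pitch_um[1], pad = 0)
    truth <- scene_transmittance(scene, 1, gt$object_pitch_um[1],
                                 nrow(rescaled$images[[1]]))
    list(geom = geom, gt = gt, scene = scene, burst = burst,
         rescaled = rescaled, recon = recon, baseline = baseline,
         truth = truth)
  })
}

# Gaussian-blob complex field (band-limited, unit background) for
# propagation property tests.
smooth_field <- function(n = 96, pitch = 2) {
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- t(xs)
  blob <- exp(-((xs - 0.6 * n)^2 + (ys - 0.4 * n)^2) / (2 * 8^2))
  optical_field(exp(1i * 0.5 * blob), pitch, 561)
}

expect_phase_close <- function(a, b, tol) {
  expect_lt(max(abs(Arg(exp(1i * (a - b))))), tol)
}
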