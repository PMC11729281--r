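# holotrack

Reconstruction and analysis for **multiplexed lensless in-line holographic
microscopy** of live cell cultures: from multi-height hologram bursts to
quantitative phase maps to per-cell migration speeds.

Lensless in-line holography records, on a bare sensor, the interference
between the unscattered illumination and the light scattered by a nearly
transparent specimen. One intensity image cannot be inverted uniquely — a
conjugate "twin" image contaminates the reconstruction — so the modelled
system captures a burst of K = 5 holograms at sample-to-camera distances
z₂ = 15…19 mm (1 mm steps, λ = 561 nm, source-to-camera ≈ 15 cm) every
5 minutes, and retrieves phase iteratively across the burst. `holotrack`
implements the complete computational chain for N parallel culture
channels, plus a physically consistent synthetic-hologram generator that
provides ground truth for every stage:

1. **Geometry** — point-source recording reduced to plane-wave equivalents:
   magnification `M = (z₁+z₂)/z₁`, effective distance
   `z_eff = z₁z₂/(z₁+z₂)`; band-limited angular-spectrum propagation.
2. **Burst conditioning** — bicubic rescaling of the ≤1.3% inter-height
   magnification spread, optional sub-pixel registration, unit-background
   normalisation.
3. **Autofocus** — dark-field gradient sharpness scanned over distance,
   parabolic refinement, and a median consensus across the K heights.
4. **Phase retrieval** — multi-height Gerchberg–Saxton with a positive
   absorption constraint (cells absorb or transmit, never amplify), against
   a single-height backpropagation baseline.
5. **Segmentation** — fixed-threshold binarisation; 8-connected labeling;
   areas classified as single cells (≤ 23 µm²), small clusters (23–46 µm²),
   or large clusters (> 46 µm²).
6. **Tracking** — globally optimal frame-to-frame assignment (gated
   Jonker–Volgenant), windowed speeds (path length over the last 50 frames
   = 250 min), per-frame medians, and cross-channel speed ratios.

Tabular results are tibbles; fitted/report objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Simulate three cultures — a control and two "treated" channels with a
2.5× faster third channel — render bursts on the fly, and run the full
pipeline:

```r
library(holotrack)

cfg  <- default_config(geometry  = list(camera_pitch_um = 1.0),
                       retrieval = list(iters = 8, pad = 0, register = FALSE))
geom <- acquisition_geometry(cfg$geometry$z1_mm, cfg$geometry$z2_mm,
                             cfg$geometry$wavelength_nm,
                             cfg$geometry$camera_pitch_um)

speeds  <- c(CTR = 0.2, NRG10 = 0.2, NRG50 = 0.5)   # µm/min ground truth
sources <- lapply(seq_along(speeds), function(i) {
  scene <- generate_scene(n_cells = 12, speed_um_per_min = speeds[[i]],
                          n_frames = 70, fov_um = 250, seed = 100 + i)
  burst_source_sim(scene, geom, seed = 1000 + i, photons = 10000)
})
names(sources) <- names(speeds)

report <- run_pipeline(sources, cfg)
report
#> <holotrack_report>
#>  channels: CTR, NRG10, NRG50
#>  median-speed ratio NRG10 / CTR = 1.040
#>  median-speed ratio NRG50 / CTR = 2.483
autoplot(report)   # per-frame median-speed dot plot with smoothed curves
```

The two printed ratios are the pipeline's recovery of the built-in truth
(1.0 and 2.5): each channel's holograms were reconstructed, segmented, and
tracked independently, speeds were computed over the 250-minute window, and
the per-frame median speeds of the treated channels were divided by the
control's. Intermediate objects are just as accessible:

```r
burst <- sources$CTR$get(1) |> rescale_burst_to_reference(geom)
z_eff <- autofocus_burst(burst, geom, pad = 0)       # K refined distances
recon <- gs_pac_reconstruct(burst, as.numeric(z_eff), n_iter = 30, pad = 0)
glance(recon)                                        # sweeps, residual, range
seg   <- segment_phase(recon)                        # label map + tibble
tidy(seg)
```

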