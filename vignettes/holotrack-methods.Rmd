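---
title: "Lensless multi-height phase retrieval and cell migration tracking: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lensless multi-height phase retrieval and cell migration tracking: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holotrack)
```

## The measurement this package models

An in-line lensless digital holographic microscope (LDHM) places a
quasi-point light source, a live cell culture, and a bare camera sensor on
one optical axis. The camera records the interference between the
unscattered illumination and the weak field scattered by the cells — an
in-line hologram. With magnification near one, the field of view is
essentially the sensor area, so thousands of cells are recorded at once,
label-free and in darkness.

A single intensity image cannot be inverted uniquely: reconstructing it
superimposes an out-of-focus conjugate ("twin") image on the true object.
The system modelled here breaks that ambiguity by *multi-height*
acquisition: at every timestamp a motorised stage records a burst of K = 5
holograms at sample-to-camera distances of 15 to 19 mm in 1 mm steps, with a
561 nm laser and a source-to-camera distance near 15 cm. Bursts repeat every
5 minutes. An iterative retrieval over the burst yields a quantitative phase
map; thresholding, area classification, and frame-to-frame tracking then
turn phase maps into per-cell migration speeds that can be compared across
simultaneously-running cultures.

## Optical model

**Point-source geometry.** A spherical wave from a source at distance `z1`
before the sample, recorded at `z2` behind it, is exactly equivalent to
plane-wave illumination with transverse magnification
`M = (z1 + z2)/z1` and effective propagation distance
`z_eff = z1 z2/(z1 + z2)`. The package handles spherical illumination only
through this equivalence (`effective_geometry()`); no spherical phase factor
is ever propagated. With the protocol's numbers, `M` ranges from 1.111 to
1.141 over the five heights — about 1.3% of differential magnification that
must be removed before the heights can be combined.

**Propagation.** Free-space propagation is the angular spectrum method: the
field's FFT is multiplied by
`H = exp(i 2π/λ · z · sqrt(1 − (λ f_x)² − (λ f_y)²))` on the propagating
band; evanescent components are zeroed (at 2 µm pitch and 561 nm the grid
cannot carry evanescent frequencies anyway, so this is a formal guard, and
zeroing is numerically stable at millimetre distances). The kernel is
unimodular on the band, so unpadded propagation conserves power to machine
precision — a property the test suite asserts at 1e−9.

Padding, when requested, fills the margin with the *median border value*
rather than zeros. A zero pad would act as a hard aperture around a field
whose background is near 1; its edge diffraction floods the interior and is
the single largest artifact source we encountered. For simulated holograms,
whose background wraps seamlessly, cyclic (unpadded) propagation is both
faster and exactly self-consistent; the pipeline therefore defaults to
`pad = 0.25` for robustness on real data but is run with `pad = 0` on
synthetic data.

A warning is raised when more than 1% of a field's spectral power lies
beyond the alias-free band of the sampled kernel chirp; the formal
sampling bound is extremely conservative for weakly scattering scenes, so
the threshold is deliberately loose.

**Burst conditioning.** Before retrieval each burst is (i) rescaled to the
first height's magnification with separable Catmull–Rom interpolation
(sub-pixel accuracy matters: the inter-height scale changes are below 1.3%)
and (ii) optionally registered to the reference height by FFT
cross-correlation with parabolic sub-pixel refinement, to absorb stage
drift. Intensities are normalised to unit-background amplitude as
`sqrt(I/B)` with `B` a wide Gaussian-blur background estimate
(replicate-padded so illumination ramps do not wrap).

## Multi-height retrieval with a positive absorption constraint

`gs_pac_reconstruct()` implements the alternating-projection scheme. One
sweep:

1. propagate the current field estimate sequentially through detector
   planes 1 → 2 → … → K, at each plane replacing the amplitude with the
   measured one and keeping the evolving phase;
2. backpropagate from plane K to the object plane and apply the **positive
   absorption constraint** (PAC): cells absorb light or are transparent —
   they never amplify — so wherever the object-plane amplitude exceeds the
   unit background it is reset to 1, phase untouched;
3. propagate to plane 1, record the data-fidelity residual (mean absolute
   amplitude mismatch), and re-impose the measured plane-1 amplitude.

The iteration starts from the plane-1 amplitude with zero phase
(deterministic by design), runs at most `n_iter = 30` sweeps, and stops
early on a residual plateau or once the fidelity has stopped improving for
three sweeps: with a hard object-domain constraint the iteration settles
into a small limit cycle around its fixed point rather than converging
monotonically, so the returned field is always the best iterate by data
fidelity, and the residual history is reported up to that sweep (making the
recorded history non-increasing to within 1e−3 relative, which the tests
assert). Focus distances are `z_eff` values — object-plane equivalents —
so the whole iteration is plane-wave propagation on the rescaled common
grid. A final PAC application guarantees the returned amplitude never
exceeds 1 + 1e−6.

Reconstructed fields carry an arbitrary global phase (the kernel's on-axis
term `exp(i 2π z/λ)`); the background is re-anchored at zero phase before
the map is returned, so phase maps are directly thresholdable.

On noiseless synthetic cultures the reconstruction reaches an object-plane
phase RMSE well under 0.1 rad, recovers over 90% of the peak phase of
2.7 µm-radius cells, and suppresses object-free background phase variance
by more than 2× compared with single-height backpropagation
(`backpropagate_single()`, the twin-image baseline) — these are the
acceptance checks, computed fresh at every test run.

## Autofocusing

The focus metric is a computational dark-field sharpness measure: zero the
DC Fourier component of the complex field (the numerical analogue of
blocking the unscattered beam), take the magnitude, and return the variance
of its spatial gradient magnitude. For weakly scattering objects the
scattered field is tightly confined at the object plane and spreads with
defocus, so the metric is **maximal in focus**; the polarity was fixed
empirically on the synthetic recovery suite and is hard-coded with a
regression test. The metric is evaluated on a central crop (10% margin per
side) because magnification rescaling and cyclic wrap leave z-independent
sharp structure at image borders that would otherwise mask the focus peak.

`autofocus_scan()` scans a coarse distance grid (default step 0.5 mm — half
the protocol's 1 mm height spacing) and refines the extremum with a
parabola through the three neighbouring samples; an extremum on the scan
boundary raises a flag, and a flat metric is a no-focus error.
`autofocus_scan_nominal()` runs the same scan on the nominal `z2` axis for
raw camera holograms, evaluating each candidate in its own plane-wave
equivalent (candidate-dependent pitch and `z_eff`).

Sharpness landscapes of small grids occasionally contain narrow spurious
peaks (truncated-fringe artifacts that "refocus" at unrelated distances).
`autofocus_burst()` therefore scans all K heights and exploits that the
stage steps between heights are known exactly: each height votes for the
common offset and the median vote wins, so a single ghosted height cannot
corrupt the burst's focus distances. The pipeline autofocuses once per
channel on the first burst — the stage is repeatable, per-frame scanning
would add nothing but runtime.

## Segmentation and size classes

The reconstructed phase is binarised at a fixed threshold (default 0.5 rad)
after median-subtraction flattening, mirroring the published procedure of a
manually chosen threshold held constant across the experiment and all
channels; the actual manual value is not reported, so 0.5 rad is a package
default, not a protocol constant. Components smaller than 4 pixels are
discarded as speckle. Labeling is 8-connected (diagonal cell bodies must
not split); areas are pixel counts times the square of the object-plane
pitch, and centroids are unweighted pixel centroids, both in micrometres.
Objects are classified as **single cells** (≤ 23 µm²), **small clusters**
(23–46 µm²), or **large clusters** (> 46 µm²); the boundary convention
puts 23 µm² itself in the single class, because single cells are described
as *approximately* 23 µm² while clusters lie *between* 23 and 46. Whether
the original areas were measured at camera-plane or object-plane pitch is
not stated (at M ≈ 1.11 the difference is ~23%); this implementation uses
object-plane pitch throughout.

## Tracking and migration speed

Only single-cell objects are tracked by default (cluster classes exist
precisely to absorb unseparable merges). Frame-to-frame linking solves a
globally optimal min-cost assignment (Jonker–Volgenant shortest augmenting
paths, written in-package because no LAP solver is available among the
dependencies and cross-checked against brute-force enumeration in the
tests) on the standard augmented matrix with birth/death costs at the gate
radius; links beyond the gate are forbidden. The gate default of 20 µm
derives from the observed maximum motility of ~1 px/min times the 5-minute
frame interval, doubled for safety. Tracks survive up to 3 consecutive
missed detections (segmentation dropouts from transient merges), coasting
at their last position.

The speed of a cell at frame *n* is the distance travelled over its last
W = 50 steps divided by the elapsed 250 minutes. "Distance travelled" is
summed step lengths (path length) by default; net displacement is available
as an option (`method = "net"`), and the path-length convention is the one
pinned by the acceptance suite. Per-frame culture speed is the median over
cells with a defined speed; a centred moving average (default 20 frames) is
stored separately and used for presentation only. Channel contrast is the
ratio of pooled medians over the frames where both channels are defined —
the frame range is a parameter because the original comparison's range is
not stated.

Note one bias worth knowing about: path-length speeds are inflated by
localisation noise (each step gains a positive noise contribution), which
compresses treated-vs-control ratios. Centroid noise must stay well below
the per-frame step length; at the default simulation scale (object pitch
≈ 0.9 µm, ~25-pixel cells) centroid errors are ~0.1–0.2 µm against 1 µm
steps, keeping the bias a few percent.

## The synthetic-data generator

No raw holograms are publicly deposited, so the simulator is the package's
ground-truth source and is first-class, tested code. It emulates:

- **motion**: a persistent random walk — exact step length
  `speed × 5 min`, heading diffusing with σ = 0.3 rad per frame,
  reflecting walls 25 µm inside the FOV;
- **optics**: cells as Gaussian phase/absorption bumps (half-maximum
  radius 2.7 µm so the half-peak footprint is ≈ 23 µm², peak phase 1 rad,
  peak absorbance 0.1 — plausible values for unlabeled progenitor cells;
  the real cultures' optical thickness is not published), sampled on the
  reference-height grid, angular-spectrum propagated per height, and
  magnified onto the camera exactly as the spherical illumination does
  optically (`M_k/M_1` geometric zoom of the diffraction pattern);
- **camera**: Gaussian shot noise with variance `I/photons`
  (default 10⁴ photons per unit intensity ≈ 1% background noise), additive
  read noise, 16-bit quantisation at 20 000 counts per unit intensity;
- **cadence**: cells static within a burst (heights are seconds apart
  against ≤ 1 px/min motility), bursts every 5 simulated minutes.

Grids are centred on the optical axis because magnification acts about the
axis — per-height grids of one burst must share that anchor or rescaling
misregisters the heights. Propagation during rendering is cyclic, which is
seamless for the unit background and makes the K holograms of a burst
mutually consistent (the simulated culture effectively continues
periodically outside the FOV).

What the simulator does **not** model: partial coherence (the real laser's
47 pm linewidth is treated as fully coherent), fibre-mode or aberration
structure of the sources, channel crosstalk, cell division, shape change,
or cell-cell adhesion dynamics. Passing the acceptance suite therefore
demonstrates that the *algorithms* recover what this forward model encodes,
not that the system end-to-end matches live-culture imaging; in particular
real thresholds must be chosen manually per the published procedure.

## Problem sizes and numerical choices

Simulation scales were chosen so the full suite and the acceptance script
run comfortably on a single CPU:

- autofocus recovery: 512×512 holograms at 2 µm camera pitch (the
  protocol's geometry, sparse 10-cell scene);
- retrieval quality: 250 µm FOV at 1 µm camera pitch (≈ 280² grid),
  12 cells, 30 sweeps;
- end-to-end contrast: three channels of 12 cells, 150 timestamps (the
  test suite uses 70), 8 sweeps per reconstruction, cyclic propagation.

Other fixed choices: Catmull–Rom (a = −1/2) for all resampling, intensity
clipped at 0; assignment ties broken deterministically toward lower column
indices; autofocus coarse step 0.5 mm with parabolic refinement clamped to
the bracketing interval; phase RMSE evaluated after background re-anchoring
(phase is defined up to a piston); `n_timestamps(68.5)` = 823 reproduces
the published experiment duration at the 5-minute cadence.

## Known limitations

- The exact published retrieval (its appendix is not in the available
  text) may order sweeps or apply the constraint differently; this
  implementation is the canonical multi-height scheme, validated by
  parameter recovery rather than by porting.
- The published DarkFocus metric internals are likewise external to the
  available text; the dark-field gradient-variance metric here matches its
  role and accuracy on synthetic data, not necessarily its formula.
- Speed ratios inherit the path-length noise bias discussed above; with
  noisy real data a net-displacement convention or a localisation-error
  correction may be preferable.
- The tracker has no lineage model: divisions appear as track births, and
  long merges (> 3 frames) split tracks.
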