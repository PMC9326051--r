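---
title: "Methods: simulating and reconstructing dynamic gated cardiac SPECT"
author: "dynspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reconstructing dynamic gated cardiac SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Dynamic myocardial perfusion SPECT with a conventional dual-head camera
faces a structural difficulty: the camera rotates slowly (90 s per
rotation), while the tracer washes in and out on a comparable time scale
and the heart beats and breathes underneath. At any instant only two
views exist, so the tomographic data are inconsistent frame by frame.
`dynspect` is a self-contained laboratory for the continuous-acquisition
answer to that problem: acquire one binned projection every 0.125 s at
0.5 degree increments, tag every frame with its cardiac and respiratory
phase, regroup frames by gate, and reconstruct each gate's activity as a
smooth function of time through a cubic B-spline expansion, with one
system matrix per gate so that the attenuation map moves with the organs.

The package simulates the entire chain forward (phantom, kinetics,
projection, noise, scatter) and solves it backward (gating, spatiotemporal
MLEM, kinetic fitting, image-quality metrics), so every claim can be
checked against a known ground truth.

# The phantom

The torso is deliberately analytic rather than anatomical: every organ is
an ellipsoid or elliptic cylinder, so each motion law can be verified in
closed form against the voxelised result.

* **Grid.** Default desk grid 90 x 60 x 55 voxels of 4.4 mm (equal to the
  reconstruction voxel and detector bin); a full mode doubles the
  resolution (180 x 120 x 110 at 2.2 mm). Both cover the same physical
  field of view.
* **Organs.** LV myocardium: prolate ellipsoidal shell (end-diastolic
  endocardial semi-axes 24/24/40 mm, epicardial 34/34/52 mm, i.e. a
  ~10 mm wall, ~97 ml cavity, ~155 ml wall). Blood pool: the shell
  interior. Liver: half-ellipsoid dome inferior-right. Lungs: two
  low-attenuation ellipsoids. Body: elliptic cylinder (260 x 190 mm),
  sized so that every projection fits the 64-bin detector at all angles.
* **Cardiac motion.** The endocardial semi-axes scale linearly from 1 at
  end-diastole to 0.737 at end-systole (0.325 s into the 1 s beat,
  giving a ~60% ejection fraction), then linearly back. The epicardial
  scale is solved at every phase so the wall volume is conserved —
  the wall thickens as the cavity empties. Myocardial label volume is
  conserved across gates to within 2% at the desk grid.
* **Respiratory motion.** Heart and liver translate along the body axis
  by `D (1 - cos(2 pi t / 5 s)) / 2` from end-exhale (D = 2.0 cm, or
  1.5 cm for the reduced-motion case); the anterior chest wall expands
  by up to 1.2 cm in synchrony.
* **Gating.** Time is discretised into 40 states: 8 cardiac sub-phases
  per beat x 5 beats per 5 s respiratory cycle, each 0.125 s long. A
  state freezes the phase at the gate's midpoint time. Displacements are
  always reported relative to the end-exhale gate, which is also the
  reference state.
* **Attenuation.** Voxelwise lookup at 140 keV: 0.155 /cm for all soft
  tissues, 0.045 /cm for lung, 0 for air. Each state carries its own
  matched attenuation map.
* **Wall defect mode.** An angular sector of the wall (default 90
  degrees) thinned by 40%, for the non-uniform-wall case.

The lungs carry background activity (they belong to "everything else"
in the four-group reduction myocardium / blood / liver / background);
their reduced density affects only attenuation.

# Tracer kinetics

The arterial input is a gamma-variate bolus `A (t/tp)^a exp(a (1 - t/tp))`
peaking at `tp` = 60 s, spliced continuously at `2 tp` onto an exponential
tail. The myocardial curve is the one-tissue compartment response

`C(t) = (1 - VL) K1 conv(Cb, exp(-k2 t))(t) + VL Cb(t)`

with ground truth K1 = 0.33 ml/g/min, k2 = 0.21 /min, VL = 0.40. The
convolution is evaluated exactly for a piecewise-linear input (per-step
closed-form weights), which makes the step-input closed form exact on the
grid and the scheme second-order for smooth inputs.

Two conventions had to be fixed here. First, the spillover weighting
`(1 - VL)` on the tissue term is the common partial-volume form of the
1TCM; it makes the fit well-defined. Second, the end-time
myocardium:blood activity ratio (3.08:1 at 6 min) cannot be imposed by
rescaling, because the myocardial curve is generated *from* the blood
curve and the ratio is scale-invariant. Instead the blood washout rate is
solved (about 0.45 /min) so that the ground-truth kinetics themselves
reproduce the 3.08:1 ratio. Liver and background are delayed first-order
low-pass responses of the input (rate 0.05 /min; delays 10 s and 30 s),
scaled to the per-case myocardium:liver (1.20:1) and
myocardium:background (TBR 8.05 / 5.11 / 10.2) end ratios; a final global
factor sets the peak total phantom activity to the case's ~25 mCi.

# Acquisition model

* **Geometry.** Two opposed heads (H-mode, 180 degrees apart) rotate
  continuously: 0.5 degrees per 0.125 s frame, 720 frames per rotation
  per head (90 s), 4 rotations (6 min). Detector bins are 4.4 mm,
  64 x 64 at the desk grid.
* **Projector.** Parallel-hole attenuated projection: the volume is
  resampled into detector-aligned coordinates (bilinear, per slice),
  weighted by the attenuation survival factor integrated from each voxel
  to the collimator face, and accumulated from the far side towards the
  detector through an incremental Gaussian cascade that realises the
  depth-dependent response `FWHM(d)^2 = 2.5^2 + (1.5 (35 + d) / 35)^2`
  (mm; intrinsic plus LEHR geometric response, radius of rotation
  320 mm). The backprojector is the exact transpose of the same discrete
  operator — the matched-pair requirement of MLEM — and the adjoint
  identity holds to machine precision.
* **Scatter.** Photon transport is out of scope, so scatter is emulated:
  the main window receives the primary plus a broad Gaussian blur of it
  (fraction 0.3, FWHM 40 mm), and the lower scatter window receives that
  component divided by the DEW factor k = 0.5. The construction makes
  the dual-energy-window correction `main - 0.5 scatter` exactly unbiased
  for the primary in expectation, so the correction pathway is testable.
* **Noise.** Per-bin Poisson draws in both windows, seeded.
* **Calibration.** One global sensitivity constant converts
  concentration x path length x time into expected counts. It is fixed
  once so that the reference case's main-window totals over the last
  minute of the scan land at the modelled system's 2.1 x 10^6-count
  level scaled by the desk-grid voxel-area ratio (8.4 x 10^6 at 4.4 mm
  voxels): the desk study keeps the counts per reconstruction cell, and
  hence the per-gate noise regime of the stabilized-window estimates,
  comparable to the full-resolution experiment it stands in for.
* **Linearity shortcut.** The expected projection of any frame is the
  TAC-weighted sum of the four tissue-indicator projections of that
  frame's gate state, so the simulator computes each (state, angle)
  tissue projection once and reuses it; the cache can be shared across
  seeds and cases. This is exact, not an approximation.

# Gating and reconstruction

Frames are atomic: the 0.125 s frame equals the gating sub-phase, so a
frame never straddles a gate. Binning by (cardiac, respiratory) tag gives
40 gates; with commensurate periods (90 s rotation, 5 s respiratory
cycle) every gate sees the same 18 azimuths, 20 degrees apart, in every
rotation and from both heads — 144 views per gate after 4 rotations, each
azimuth measured 8 times at different tracer times.

Within a gate the activity is `A(x, t) = sum_n a_xn V_n(t)` with 9
clamped cubic B-splines on [0, 360] s (interior knots 30, 60, 100, 180,
270 s — denser around the blood-pool peak; the knot vector is a config
item). The coefficients follow the multiplicative EM update for the
Poisson likelihood with a linear basis expansion — the numerator
backprojects the count ratios weighted by the basis values at the frame
times, the denominator is the basis-weighted backprojection of ones. The
update preserves nonnegativity and never decreases the likelihood (the
trace is recorded per iteration and asserted in the tests). Gates are
reconstructed independently — the six-dimensional problem (space, time,
cardiac phase, respiratory phase) is decoupled into per-gate 4D problems,
with the gate-matched attenuation map inside each gate's system matrix.
An ungated mode pools all frames with a time-averaged attenuation map for
comparison; on a static scene it agrees with the gated result, on a
moving one it blurs the wall.

Numerical choices: initialisation is 1 inside the body support and 0
outside; a 1e-12 guard protects the ratio denominators; voxels with zero
sensitivity are frozen at 0. The depth range of the per-gate operator is
trimmed to the phantom's transaxial support, which changes nothing on
supported volumes and saves ~40% of the runtime.

**Iteration count.** The default for quantitative runs is 150 iterations.
This is a measured choice, not a convention: with a ~15 mm system
response at the heart (LEHR at 32 cm radius of rotation) and a ~10 mm
wall, MLEM recovers the myocardial activity slowly — after a few tens of
iterations the ROI estimate is still far below its converged value, and
it enters the regime of the headline bias bound only in the low hundreds
of iterations; 150 was fixed from the noiseless convergence curve.
Exploratory work can use fewer iterations (`mlem_spatiotemporal()`
defaults to 30), but quantitative bias statements are only meaningful in
the converged regime.

**Post-filter.** Reconstructions exported for display are smoothed with
the 4.5 mm FWHM spatial Gaussian (9-point kernel; sub-voxel sigma at
4.4 mm voxels). The filter is spatial-only: temporal smoothness is
already enforced by the spline model. Quantitative metrics are computed
on the unfiltered coefficients by default (`filter = FALSE` in the
`compute_*` functions), matching standard quantification practice;
passing `filter = TRUE` reproduces the filtered-image reading.

# Kinetic fitting and evaluation

Reconstructed TACs are ROI means over the eroded ground-truth myocardium
and blood labels (erosion by one voxel removes the partial-volume rim and
the manual-segmentation confound). The 1TCM with spillover is fitted by
bounded least squares (K1, k2 in [0, 3], VL in [0, 1]) from five fixed
starts, best residual kept — deterministic by construction. Fits use the
full 0.125 s grid over the 6 min scan; fitting only the first 6 min of a
20 min tracer history is known to inflate k2, and that property is
reproduced rather than corrected.

Image-quality metrics are read from a **stabilized-window
reconstruction** (`recon_stabilized()`): only the last-minute frames
enter, and the temporal basis is a single constant over [300, 360] s, so
each gate's estimate is effectively a static reconstruction of the
stabilized phase at full angular coverage (the last minute spans two
thirds of a rotation per head, which with the opposed head covers all 18
of a gate's azimuths). This matters: reading the same window off the tail
of the full-scan spline fit is ill-conditioned — the clamped end basis is
constrained by few late frames, so noise can tilt the fitted tail
substantially from seed to seed — while the stabilized-window estimate
is well conditioned at the same angular coverage. The full-scan spline reconstruction
remains the tool for time-resolved questions (TAC extraction, kinetic
fitting).

Metrics over the eroded myocardial ROI, in the last-minute stabilisation
window [300, 360] s (evaluated every 5 s):

* **MSA** — ROI mean of the time-averaged activity;
* **SNR** — MSA divided by the spatial standard deviation over ROI
  voxels of the time-averaged activity;
* **Bias** — percent deviation of the MSA from the generator myocardial
  TAC mean over the same window.

These formulas are fixed here as the simplest definitions consistent with
"mean stabilised activity"; the source system they emulate does not print
them. The respiratory motion-fidelity trace segments the reconstructed LV
(half-maximum threshold inside a ground-truth heart mask) and reports the
axial centroid per respiratory gate relative to end-exhale; it is
compared against the raised-cosine law sampled at the gate midpoints.

# What the synthetic data do and do not show

The generator reproduces the study conditions — geometry scale, motion
amplitudes and periods, count levels, gating structure, energy-window
scatter fractions — with analytic organs and emulated scatter. Passing
tests therefore demonstrate the correctness of the gating/reconstruction/
fitting machinery and the qualitative phenomenology (motion blur without
gating, TBR orderings, bias convergence), under a matched projector:
simulation and reconstruction share the same discrete operator, so
model-mismatch effects present in real data (septal penetration, true
scatter spectra, detector nonlinearity, anatomical texture) are absent.
Absolute noise levels are realistic only to the extent that the single
count calibration is; per-patient anatomy, arrhythmia and irregular
breathing are out of scope by design.

# Problem sizes used in the shipped checks

The test-suite and the acceptance script run at desk scale: the
90 x 60 x 55 grid, the full 2880-frame schedule, stabilized-window
reconstructions of two to five gates at 150 EM iterations (three noise
seeds and both cardiac phases for the headline bias), and miniature
(24 x 20 x 14 and 2D) phantoms for the structural and oracle tests.
These sizes were chosen so a complete run stays desk-friendly while
every quantitative claim is made in the converged regime of the
reconstruction.

# Known limitations

* The cardiac deformation is a radial scaling law with wall-volume
  conservation; twist and longitudinal shortening are not modelled.
* Scatter emulation is constructed for DEW-unbiasedness, not for
  spectral realism; septal penetration and detector energy sampling are
  omitted.
* The matched-operator setting (same projector for simulation and
  reconstruction) is an inverse-crime configuration: real-data biases
  will be larger.
* Per-gate reconstructions are independent; no information is shared
  across gates, which wastes counts relative to a fully coupled 6D
  model.
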