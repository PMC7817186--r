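---
title: "Models and methods behind istomo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind istomo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`istomo` analyses effector/target cell conjugates and their immunological
synapse (IS) in label-free refractive-index (RI) tomograms. This vignette
explains the models the package implements, the assumptions behind them,
the tunable parameters, and the design decisions taken where the
literature leaves the choice open. Everything quantitative stated here is
computed by the test suite or by `scripts/acceptance.R`.

## 1. Tomographic model

ODT measures complex fields of a sample illuminated from many angles
(49 by default: one normal-incidence beam plus 48 on a cone at the
illumination NA, azimuthally uniform). Under weak scattering the Rytov
field ψ = log(u/u_inc) is linear in the scattering potential
f(**r**) = k₀²(n² − n_m²), with k₀ = 2π/λ (λ = 532 nm by default) and
medium RI n_m (default 1.337, standard culture medium; the exact value is
a configuration input). The Fourier diffraction theorem maps the 2D
transform of u_inc·ψ onto the Ewald half-sphere cap of its illumination
with the weight i/(2k_z). We verified this normalization against the thin
homogeneous slab, whose transmitted phase must be 2π·Δn·d/λ.

**Discretization.** The forward model samples the object's DFT at the
*nearest spectrum grid point* of each cap frequency, and the
reconstruction deposits measured values at that same point, averaging
overlaps by occupancy counts. Forward and inverse are therefore a
consistent discrete pair: round-trip errors come only from the unsampled
region (the missing cone), not from interpolation mismatch. Trading
interpolation accuracy for exact consistency is deliberate — it makes the
reconstruction testable against analytic phantoms (a rasterized ball's
DFT matches the closed-form ball transform on the cap to about 2% RMS at
64³, with 3× edge supersampling of the phantom).

**Missing cone.** Frequencies outside the illumination/detection apertures
are never measured, which elongates reconstructions axially. The package
fills them by alternating projections: clamp the RI contrast to ≥ 0 in
object space (cells are denser than medium), then restore the measured
Fourier samples. Defaults: 100 iterations, stop when the relative object
change falls below 1e-6; neither value is prescribed by the measurement
physics, they simply put the projection fixed-point well below the
voxelization error. On a 64³ sphere phantom with Δn = 0.02 and 49 views
this cuts the in-support RMSE about fivefold, to under 10% of the true
contrast; the tests assert the ≤ 30% contract.

**Resolution.** The lateral Nyquist period is λ/(2(NA_ill + NA_det)).
Because the axial support depends on how the scan fills the Ewald shells,
`compute_resolution()` exposes two axial variants (both cones, or the
detection cone alone). The widely quoted 125/471 nm figures for this type
of instrument are not derivable from λ = 532 nm and any single stated NA
pair, so the package documents them but asserts neither.

**Dry mass.** Protein concentration is c = (n − n_m)/α with
α = 0.185 mL/g, reported in fg/µm³ (1 g/mL = 1000 fg/µm³). Negative
contrasts clamp to zero and the clamped count is logged. The assumption is
a constant RI increment across the cell — good for protein-dominated
cytoplasm, biased wherever lipids dominate below optical resolution.

## 2. Classical annotation and consensus

Training labels come from a deliberately simple, reproducible pipeline
with four manual choices: per-cell seed points, an RI threshold, a merge
radius, and a Gaussian smoothing σ. The volume is smoothed, thresholded,
closed with a Euclidean ball of the merge radius (closing, not bare
dilation, so cell volume is not inflated; whether the original recipe
dilates the binary foreground or the grayscale volume is ambiguous — we
chose the binary foreground), and split by a marker-based watershed
flooding the negated distance transform from the seeds.

Two discretization details matter here. First, the exact Euclidean
distance transform takes heavily quantized values (square roots of small
integers), so the flooding front crosses large plateaus of tied priority;
claiming those plateaus in voxel scan order biases the boundary
directionally, so ties instead go to the flood whose seed is nearer
(then insertion order) — deterministic and directionally unbiased.
Second, the claim that the watershed boundary is the analytic mid-plane
of two equal spheres is a *reflection-symmetry* argument, and the voxel
lattice is only reflection-symmetric about planes aligned with the grid.
The tests therefore assert the ≥ 95%-within-one-voxel property across 20
randomized lattice-symmetric conjugates (random radius, contact depth,
grid axis and polarity, seeds at the exact centres); for oblique
conjugate axes the measured fraction is typically 0.8–1.0 because
sub-voxel lattice asymmetry at the contact rim shifts individual boundary
voxels — an intrinsic property of digital watershed on a quantized
distance map, observable even with exactly mirror-symmetric seeds.

STAPLE estimates a consensus segmentation and each rater's sensitivity
p and specificity q by EM. The prior is the mean foreground fraction of
the raters, initial p = q = 0.9, convergence when parameters move less
than 1e-6, cap 100 iterations; the per-iteration log-likelihood is
recorded and must be non-decreasing. With 5 simulated raters at a 10%
symmetric flip rate the estimates recover 0.90 within ±0.03.

## 3. Signed-distance regression

Voxel-wise class labels fragment badly on touching cells, so the package
regresses a *signed Euclidean distance map*: +d to the nearest background
voxel inside the effector, −d inside the target, exactly 0 on background.
Cell identity lives in the sign; instance separation becomes a regression
problem with a well-behaved target. Distances are kept in voxel units so
a trained model transfers across magnifications; the post-processing
threshold (54.5 nm ≈ a quarter of the 218.5 nm default pitch — the
literal value is taken as authoritative) is applied after conversion by
the pitch.

**Loss.** Boundary-weighted L1:
w(v) = 1 + w_b·exp(−d_b(v)²/(2σ_b²)) with d_b the distance to the nearest
cell-boundary voxel; defaults w_b = 9, σ_b = 2 voxels. The weight's
functional form is our choice (the original recipe cites prior work
without formulas); it concentrates gradient signal where segmentation
errors actually matter.

**Architecture.** A U-shaped encoder/decoder. Each encoder scale applies
a 3×3×3 convolution (stride 2 below the top scale) and a ResNet block;
each skip connection passes a large-kernel "global convolution" module
factorized into k×1×1 / 1×k×1 / 1×1×k convolutions (internal width equal
to the skip channels); the decoder upsamples nearest-neighbour and fuses
skips by addition. The full-scale recipe (5 levels, 32–512 filters, GCN
kernels 13, 13, 9, 7, 5) is available as `network_config_full()`; the
default is a desk-scale 3-level network (8/16/32 filters, kernels 7/5/3,
32³ patches) that trains on one CPU in minutes. Convolutions are im2col +
BLAS GEMM with hand-written exact backprop (verified against numerical
differentiation to ~1e-8 relative).

**Optimization.** Adam with step decay (×0.5 every 50 epochs) and early
stopping when the internal validation loss has not improved by more than
`min_delta` (1e-8) for 5 consecutive epochs; the best-validation
checkpoint is returned. The configured defaults are the full-scale recipe
(lr 1e-3, β₁ = 0.5, β₂ = 0.99, ~85/15 split). For the desk-scale runs in
the tests we instead use β₁ = 0.9, β₂ = 0.999 for 40 epochs: with only
~300 gradient steps the low-β₁ setting is still far from convergence,
while the heavier momentum reaches held-out mask Pearson ≥ 90% inside the
CPU budget. One seed governs split, initialization and augmentation.

**Augmentation.** Right-angle rotations in the lateral plane, lateral
(never axial — the coverslip breaks z-symmetry) reflections, optional
random crops, and optional elastic deformation. After elastic warping the
distance targets are *recomputed* from the warped masks rather than
warped numerically, since warping does not commute with the distance
transform.

**Tiled inference.** Tiles carry a context margin equal to the network's
analytic receptive-field radius rounded up to the stride lattice, so
every core voxel sees exactly the context it would see in a full-volume
pass: tiled and untiled inference agree to machine precision. For the
desk-scale network the receptive field is comparable to the test volumes,
so tiling matters only for wide-area maps.

## 4. Post-processing and quantification

Masks come from thresholding the regressed map at ±54.5 nm, keeping each
cell's largest 26-connected component (fragment removal is logged and can
be disabled). The IS is the overlap of the two masks dilated by a digital
Euclidean ball of 2 voxels (437 nm, comparable to the axial resolution);
surface and interior split by erosion with the 6-connected cross of
radius 1 voxel (218 nm). The structuring elements are our choice — the
sizes are prescribed, the elements are not — and are recorded in output
metadata.

Quantities: synapse area is *en-face projected occupancy* — the IS mask
is projected along the inter-centroid axis (snapped to the nearest grid
axis, since the original analyses never define the projection direction)
and the occupied pixel count is multiplied by the lateral pixel area.
Mean surficial density is shell mass divided by projected shell area (the
maximum en-face projection map is produced for visualization, not for the
mean). Total IS protein integrates c over the IS. The centre of mass is
the density-weighted mean voxel position of the cell interior.

Kinetics fit the two-parameter saturating hyperbola
y(t) = y_max·t/(t + τ½) by Levenberg–Marquardt least squares with
multistart (y_max₀ = max(y); τ₀ ∈ {t_med/3, t_med, 3·t_med}; best SSE
wins, ties to the smaller τ½); ρ is the Pearson correlation of fitted
versus observed values (the most defensible reading of the ρ quoted with
such fits). Rate windows average d over 10-s spans at 0 s and 100 s with
linear interpolation at the edges. Wilcoxon comparisons use the
signed-rank test (paired) or rank-sum test (unpaired), exact for n ≤ 25
without ties, normal approximation with tie correction otherwise.

## 5. The phantom generator

The generator builds two quasi-spherical cells (cytoplasm, concentric
nucleus-like core at +0.005 RI, optional high-RI granules at +0.015)
with positive contrast over the medium, rasterized at voxel centres;
overlap voxels go to the nearer centre with the effector winning exact
ties. Time-lapse series prescribe the contact-disc area
A(t) = A_max·t/(t + τ½) — realized by interpenetrating the spheres to the
separation whose radical-plane disc has that area — and each cell's
*density-weighted centroid* displacement Δd(t), another hyperbola. The
default kinetics parameters are the fitted values of measured CAR-T /
target conjugates (A_max = 106.16 µm², τ½ = 39.63 s; Δd_max = 7.48 and
1.74 µm, τ½ = 37.84 and 14.56 s), so synthetic series resemble measured
ones; realizing the default area requires cells of ~6.5–7.5 µm radius
(the `simulate` subcommand's full-scale spec), while tests use a
geometrically similar desk-scale configuration (64×64×48 voxels,
2.8 µm cells, A_max = 10 µm²).

Two subtleties make the centroid kinematics exact. First, truncating a
sphere by the contact plane moves its centroid; the correction
(cap first moment πa⁴/4, weighted by compartment densities) is applied so
that the *density-weighted centroid*, not the sphere centre, follows the
hyperbola — exact for spherically layered cells, which is why the
kinetics tests use granule-free conjugates. Second, prescribing both
displacement magnitudes *and* the area-derived separation over-determines
collinear motion; the effector centroid therefore moves along the initial
conjugate axis toward the target (the physically sensible direction — the
effector pushes its target), and the target's direction is solved per
frame from a 1-D root so that its displacement magnitude and the
separation both hold. A lateral effector direction violates the triangle
inequality between the three constraints at both desk and full scale and
is rejected at generation time with a geometry error.

**What the phantoms do not emulate:** realistic organelle morphology,
sub-resolution membrane structure, optical noise beyond additive Gaussian
RI/field perturbations, segmentation-adversarial texture, or cell shape
change beyond rigid motion plus truncation. Passing the phantom suites
therefore demonstrates correctness of the algorithms under their stated
models, not segmentation accuracy on measured tomograms — the latter
depends on a trained full-scale model and real annotated data.

**Synapse-area measurement in the kinetics tests** uses the phantom's
true contact-disc mask (stored in every `phantom_truth`) rather than the
dilation-overlap IS: at desk scale the 2-voxel dilation overlap adds a
curvature-dependent rim band comparable to the disc itself, which is a
property of the IS *definition*, not a measurement error. The
dilation-overlap IS is tested separately for its own geometry.

## 6. Numerical choices and degenerate inputs

- Distance transforms are exact (separable parabolic-envelope algorithm),
  validated against exhaustive nearest-background search on hundreds of
  small random masks.
- Watershed and quality-guided phase unwrapping break ties by
  deterministic insertion order; identical inputs give identical outputs.
- Boundary voxels for the displacement error are mask voxels 6-adjacent
  to in-grid background, so the field-of-view walls are not counted as
  boundaries (a half-space shifted by one voxel has BDE exactly 1).
- Pearson mask correlation is computed over the full common grid;
  constant masks raise a typed error rather than returning NaN.
- Volumes are stored as 32-bit float TIFF stacks with a JSON sidecar
  (pitch, medium RI, affine storage mapping with a power-of-two scale, so
  the mapping adds no rounding beyond float32 itself). TIFF + sidecar was
  chosen as the single native container; mask sets use one 8-bit TIFF
  with bit-flag labels (effector 1, target 2, IS 4) because the IS
  legitimately overlaps the cells and a flat 0–3 labelling could not
  round-trip losslessly.
- Degenerate inputs raise classed conditions (`istomo_*_error`)
  throughout: empty foregrounds, seeds outside the foreground, zero
  carrier, zero interior mass, all-zero paired differences, infeasible
  kinetics.

## 7. Problem sizes

The shipped tests run at sizes chosen so the whole suite completes in
minutes on one CPU: 64³ reconstruction round trips with 49 views, 101
desk-scale time-lapse frames at 64×64×48, a 3-level network trained on
sixteen 32³ phantoms for up to 40 epochs and evaluated on four held-out
conjugates (mask Pearson ≥ 90%, boundary displacement ≤ 2 voxels), and
20 randomized watershed phantoms at 44³. The full-scale network and
phantom configurations are provided for real-data work but are not
exercised by the tests.

## 8. Known limitations

- The forward model is single-scattering; strongly scattering samples
  (contrast beyond ~0.05) violate the Rytov assumption and are flagged.
- Nearest-voxel spectrum gridding trades some high-frequency fidelity for
  exact forward/inverse consistency; trilinear spreading would lower
  interpolation error but break the round-trip identity the tests rely
  on.
- The desk-scale network shows the method end-to-end but is far smaller
  than the full-scale recipe; no claim is made about measured-data
  accuracy.
- Active-contour refinement and temporal-consistency smoothing of masks
  are out of scope.
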