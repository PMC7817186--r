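# istomo

Label-free 3D segmentation and kinetic analysis of immunological synapses
(IS) from refractive-index (RI) tomograms.

When an effector immune cell (for example a CAR-T cell) engages its target,
the two cells form a tight junction — the immunological synapse — whose
area, protein content and mechanics evolve over seconds to minutes. Optical
diffraction tomography (ODT) images this process without labels by
reconstructing the 3D refractive index n(**r**) of the conjugate, and the
linear RI increment α = dRI/dc (0.185 mL/g for protein) turns RI contrast
into protein concentration. The hard part is computational: the two
adjoining cells have no visible boundary in RI, so ordinary thresholding
cannot separate them, and every downstream quantity (synapse area, synaptic
protein density, centre-of-mass mechanics) depends on that separation.

`istomo` implements the full analysis chain in R:

- **Reconstruction** — phase retrieval from off-axis holograms, the Rytov
  field ψ = log(u/u_inc), mapping of each angled view onto its Ewald cap
  via the Fourier diffraction theorem, and Gerchberg–Papoulis-style
  non-negativity regularization of the missing cone. Resolution bounds
  follow the Nyquist sampling period, λ/(2(NA_ill + NA_det)) laterally.
- **Annotation** — the classical 4-hyper-parameter pipeline (seeds, RI
  threshold, merge radius, smoothing σ) driving a marker-based 3D
  watershed, plus STAPLE consensus over repeated annotations.
- **Instance segmentation** — regression of a signed Euclidean distance
  map, y(**v**) = +d(**v**) inside the effector, −d(**v**) inside the
  target, 0 on background, by a U-shaped 3D conv-net with ResNet encoder
  blocks and large-kernel separable (GCN) skip modules, trained with a
  boundary-weighted L1 loss and Adam. The conv kernels, backprop and
  optimizer are implemented in the package (C++ via RcppArmadillo).
- **Post-processing** — masks by thresholding at 54.5 nm; the IS as the
  overlap of the two masks dilated by 2 voxels (437 nm); surface/interior
  split by 1-voxel erosion.
- **Quantification** — en-face synapse area, surficial and intracellular
  protein densities, total IS protein, density-weighted centre-of-mass
  trajectories, saturating-hyperbola fits y(t) = y_max·t/(t + τ½),
  10-s rate windows, and Wilcoxon comparisons.
- **Evaluation** — 3D Pearson correlation of volumetric masks and the
  boundary displacement error (BDE).
- **Phantoms** — a synthetic two-cell conjugate generator with exact
  ground truth (masks, signed distances, contact disc, kinematics), so the
  entire pipeline is testable without any measured data.

## Worked example

Simulate a noiseless conjugate time-lapse whose contact-disc area grows as
a saturating hyperbola, measure it back through the quantification chain,
and refit the kinetics:

```r
library(istomo)

spec <- phantom_spec(
  shape = c(64, 64, 48), pitch = 218.5,
  effector = phantom_cell(center = c(-2900, 0, 0), radius = 2800,
                          cyto_ri = 1.360, core_radius = 1100),
  target   = phantom_cell(center = c(2900, 0, 0), radius = 2800,
                          cyto_ri = 1.350, core_radius = 1100))
kin <- kinetics_spec(a_max = 10, tau_area = 39.63,
                     dd_max = c(1.5, 0.6), tau_disp = c(37.84, 14.56))
frames  <- make_timelapse(spec, kin)
metrics <- quantify_timelapse(frames,
                              is_masks = lapply(frames, `[[`, "interface"))
fit_hyperbola(metrics$time_s, metrics$area_um2)
#> y(t) = y_max t / (t + tau):  y_max = 9.835, tau_1/2 = 38.31 s, rho = 0.998

dens <- ri_to_density(frames[[50]]$tom, alpha = 0.185)
max(dens$values)           # peak intracellular density, fg/um^3
#> 151.4

compute_resolution(volume_metadata())
#> lateral 110.8 nm, axial 177.9 nm (Nyquist sampling periods)
```

The fitted `y_max` (9.84 µm² vs the prescribed 10) and `τ½` (38.3 s vs
39.63 s) recover the generating kinetics to within the voxelization error
of a 218.5 nm grid; `rho` is the Pearson correlation between the fitted
curve and the measured series.

Training and applying the segmentation network on synthetic conjugates
(CPU, minutes):

```r
dataset <- lapply(1:16, function(i)
  make_conjugate(istomo:::toy_phantom_spec(32L, 100 + i)))
model <- train_distnet(dataset, network_config(),
                       train_config(beta1 = 0.9, beta2 = 0.999,
                                    max_epochs = 40, val_fraction = 0.25))
pair  <- masks_from_distmap(infer_distnet(model, dataset[[1]]$tom))
is    <- synapse_mask(pair)             # 2-voxel dilation overlap
```

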