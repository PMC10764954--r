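---
title: "Reconstructing short-scan, offset-detector cone-beam CT with an attenuation field network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing short-scan, offset-detector cone-beam CT with an attenuation field network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cbctafn)
```

## The problem

An upright dedicated breast CT system would acquire cone-beam data over a
*short scan* (less than 360 degrees of source rotation) with a *laterally
offset* flat-panel detector (each view covers only part of the field of
view). Either incompleteness alone is classically recoverable: fan-beam data
are two-fold redundant, `f(beta, gamma) = f(beta + pi + 2 gamma, -gamma)`,
and a weighting function with unit pair sums
(`w(beta, gamma) + w(beta + pi + 2 gamma, -gamma) = 1`) restores a correct
FDK reconstruction from a short scan (Parker-type weights) or from an offset
detector in a full scan. Both incompletenesses *together* leave rays with no
acquired complement, and no weighting can recover them.

This package implements the whole chain on synthetic digital breast
phantoms:

1. the acquisition geometry and the emulation of short-scan + offset
   acquisitions from complete data (`cone_beam_geometry`,
   `emulate_short_scan_offset`);
2. a ray-marching forward projector under the Beer-Lambert model
   (`forward_project`, `to_intensity`/`from_intensity`);
3. FDK filtered backprojection with cosine weighting, Ram-Lak filtering and
   redundancy weights applied pre- or post-convolution (`fdk_reconstruct`,
   `parker_weight_map`, `offset_weight_map`);
4. a per-scan, self-supervised *attenuation field network* (AFN) that learns
   a continuous attenuation function from the acquired rays only, then
   synthesizes the missing sinogram pixels so that the spliced, complete
   data can be reconstructed by any analytic method (`train_afn`,
   `synthesize_projections`, `splice`);
5. image-quality metrics and the paired statistical harness
   (`noise_variance`, `sdnr`, `fwhm_profile`, `paired_compare`).

## The attenuation field network

The AFN represents the attenuation coefficient mu(r) (1/cm) as a function
of the physical coordinate r through a multiresolution hash-grid encoding
followed by three fully connected ReLU layers of width 64 and an exponential
output activation (nonnegativity by construction; the activation's
derivative is clipped at 15 during backpropagation to avoid exploding
gradients). A training example is one ray from the source to an acquired
detector pixel: the ray is clipped to the cylindrical imaging FOV,
partitioned into `k` equal bins with one stratified sample per bin, the
network is queried at the samples, and the rendered line integral
`sum_i h(t_i) |t_{i+1} - t_i|` (the last interval closed at the exit point;
lengths in cm) is compared with the measured value by squared error. Only
acquired pixels ever contribute to the loss; self-supervision comes from the
internal redundancy of cone-beam data.

Training iterates, per epoch, over all acquired views; per view one batch of
`rays_per_batch` pixels is drawn without replacement and non-repeating
across epochs until the view's pool is exhausted (then reshuffled). The
optimizer is Adam (`beta1 = 0.9`, `beta2 = 0.99`, `eps = 1e-15`) with weight
decay `1e-6` on the MLP weight matrices and a learning rate of `1e-3`
decayed by one third every 50 epochs. View order is fixed by default
(`shuffle_views` enables per-epoch shuffling); the whole run is
deterministic given (config, data, seed).

Implementation notes:

* The performance-critical chain (hash encoding, MLP forward/backward, ray
  rendering, loss gradient, encoder scatter) is fused into one compiled
  call per batch, single-precision internally; it is unit-tested against a
  modular double-precision path and against central finite differences.
* The last layer is initialized to zero so the untrained field is the unit
  constant `exp(0) = 1`; cold starts are reproducible.
* Coordinates are mapped from the FOV cylinder into the unit cube per axis
  with a 5% margin before encoding.
* Inference (volume query, sinogram synthesis) uses deterministic bin
  midpoints; stratified jitter is a training-time variance-reduction device.
* Encoder scale: the finest grid level should resolve the reconstruction
  voxel pitch. The desk preset spans the 281 mm FOV cube with 128 cells
  (~2.2 mm) for 2 mm voxels; an earlier 72-cell choice demonstrably blurred
  5 mm calcifications.

## Redundancy weights

Both weight families are built from the half-sine transition
`s(x) = sin(pi x / 2)`.

The **offset-detector weight** is a function of the fan angle only: 0 on the
fully truncated side (`gamma <= -gamma_t`, with `gamma_t` at the truncation
edge), a transition `(1 + s(x))/4` on `[-gamma_t, -gamma_s]` with the
argument mapped as `x = 2 (gamma + gamma_t)/(gamma_t - gamma_s) - 1` (the
printed form of this argument in the source literature is discontinuous at
the branch ends; continuity is the weight's purpose, so the mapped form is
used), a central plateau of 1/2, and the mirrored complement
`w(gamma) = 1 - w(-gamma)` on the measured side. `gamma_s` defaults to
`gamma_t / 2`. A `literal` mode reproduces the printed quarter-scale variant
(pair sums of 2, jump at 0) for fidelity experiments only.

The **short-scan (modified Parker) weight** applies the same transition
family in the view-angle dimension. For each fan angle the redundantly
measured interval at the start of the arc carries a ramp `0 -> 1/2` of
angular width `gamma_max - gamma`, a plateau at 1/2 whose width equals the
over-scan `arc - (180deg + 2 gamma_max)`, and a ramp `1/2 -> 1`; the end of
the arc mirrors it. Pair sums are exactly 1, the weight vanishes at the arc
boundaries, rays without an acquired complement get weight 1, and the
half-weight plateau appears exactly when the arc exceeds the classic Parker
limit. A full 360-degree arc has no boundary and yields the constant 1/2,
which also makes "unit-pair weighted" and "unweighted" full-scan FDK
identical by construction.

A note on *verifying* the pair-sum condition: evaluated analytically on a
dense `(beta, gamma)` grid the deviation is at machine precision. Evaluated
through the *gridded map* with view interpolation
(`verify_complementarity(method = "interp")`) the deviation is dominated by
the transition width `gamma_max - gamma`, which tends to zero toward the
edge fan angle: no realistic view spacing resolves those ramps, so the
interpolated diagnostic is only meaningful away from the outermost columns.

## FDK

Standard Feldkamp reconstruction on the virtual detector at the isocenter:
cosine pre-weighting `d_so / sqrt(d_so^2 + u'^2 + v'^2)`, row-wise Ram-Lak
filtering realized from the closed-form spatial kernel (h(0) = 1/(4 du^2),
odd taps `-1/(pi k du)^2`) via zero-padded FFT (next power of two at least
twice the row length - a bare `|f|` gain would bias DC), optional
redundancy weighting before or after filtering, then voxel-driven
backprojection with `d_so^2/U^2` distance weighting and bilinear detector
interpolation. The angular step is `2 pi / n_views` of the full-scan grid;
when no weight map is supplied the full-scan two-fold redundancy factor 1/2
is applied instead. Line integrals are in mu(1/cm)-times-cm while the
geometry is in mm, so the inversion carries an explicit factor 10 to report
1/cm. Post-convolution weighting is reserved for complete (spliced) data;
pre-convolution weighting of zero-filled data reproduces the classical
baselines.

## The synthetic phantoms

No clinical data ship with the package; the generator emulates the
acquisition the clinical protocol describes: 300 views over 360 degrees, a
1024 x 768 panel at 0.388 mm pitch, source-axis 650 mm, source-detector
898 mm, half-cone geometry with the chest wall at detector row 0
(`geom_kbct1000`). The phantom is a half-ellipsoid pendant breast with a
skin shell, soft-edged fibroglandular blobs and spherical calcifications;
default soft-tissue attenuations (adipose 0.20, fibroglandular 0.27, skin
0.28 1/cm) sit inside the usual breast-CT display window, calcifications at
1.20 1/cm. These values are configuration, not measurements. Supersampled
rasterization (2x per axis) gives partial-volume edges so resolution loss
is visible.

The desk preset (`desk_experiment`) keeps the physical panel size (all fan
and cone angles, hence all weights, unchanged) but bins the detector to
128 x 96, uses 60 views, a 96^3 x 48 grid at 2 mm, AFN with a 2^16 hash
table, 8 levels up to 128 cells, k = 64 samples per ray, batches of 1024
rays and 30 epochs. The phantom is a large breast (17 cm chest-wall
diameter, inside the clinical 11.8-18.3 cm range) deliberately big enough
that the one-quarter detector truncation cuts into its shadow - with a
small object the truncation removes no information and the Parker-only
baseline would trivially succeed, which is not the regime of interest.

What the phantoms do *not* emulate: anatomic texture beyond smooth blobs,
scatter and beam hardening (primary-beam model only, as assumed throughout),
detector blur, lag or gain non-uniformity, and patient motion. Passing the
phantom suite therefore demonstrates the *geometry and data-consistency*
behavior of the methods, not clinical image quality.

## Numerical choices

* Forward projector: midpoint rule on uniform bins, trilinear interpolation,
  zero outside the grid; validated against the analytic ellipsoid chord,
  where agreement is quadrature-limited for interior rays (median relative
  error at the 1e-3 level at 512 samples) and rasterization-limited for
  grazing rays - the oracle comparison is therefore reported over rays with
  a substantial chord.
* Intensity model: Poisson draws of 0 are clipped to 0.5 counts before the
  log (configurable).
* Ray-FOV misses yield `entry_t == exit_t` and render 0.
* FWHM profiles sample at half the voxel pitch, estimate background from the
  window's end quarters, and interpolate half-maximum crossings linearly.
  A single few-mm object at 2 mm voxels is quantization-limited, so
  per-case FWHM is the mean over the phantom's calcifications.
* Normality gating for the paired comparison tests the *differences*
  (the assumption the paired t-test actually makes).

## Design points that were genuinely open

* The minimum short-scan arc is exposed as a parameter
  (`180deg + 2 gamma_max` is enforced, nothing is hard-coded to 204deg).
* `gamma_t` is taken at the truncation edge (outer edge of the last missing
  column); `gamma_s` defaults to half of it.
* Truncated columns are counted as `round(2 offset / pitch_u)`; the
  clinical emulation's 256-of-1024 arises when the 40 cm panel is treated
  as exactly 1024 columns, so the emulator also accepts an exact column
  count and the pipeline uses counts.
* The activation-gradient clip is applied to the derivative of the
  exponential (`min(exp(z), 15)`).
* View order during training is fixed (a shuffle flag exists); when a view's
  unseen-pixel pool runs out mid-batch it is reshuffled and drawing
  continues.
* Serialization uses NIfTI (volumes), raw float32 + JSON sidecar
  (projections) and JSON (geometry, AFN checkpoints).

## Problem sizes and limitations

The test-suite and acceptance problem sizes (desk preset above; a 72^3-ish
sphere scene for the classical-redundancy checks; a 32^2-detector scene for
the training unit test) were chosen so the whole suite runs on one CPU in
minutes while every claim stays at the stated tolerance.

Known limitations at this scale:

* In-plane (mediolateral) resolution of the AFN-inpainted reconstruction is
  limited by azimuthal sampling: with 60 views, the 90-degree gap removes
  precisely the view directions that carry mediolateral frequencies, and
  the synthesized gap views cannot fully restore them - the calcification
  FWHM along ML broadens by roughly a fifth while the superior-inferior
  FWHM is preserved within a percent. The acceptance suite asserts SI
  tightly and ML only coarsely; at clinical view counts this asymmetry is
  expected to shrink (the clinical study reports a null difference), but
  that regime is out of reach on one CPU.
* The AFN reconstruction is least constrained near the periphery and the
  chest wall (data there are most under-sampled), mirroring the behavior
  reported for large breasts.
* No scatter or beam-hardening modeling anywhere; a primary-beam-plus-
  scatter loss would be a model change, not a parameter change.

## Reproducing the experiments

```{r example}
cfg <- desk_experiment(master_seed = 1)
ref <- run_reference(cfg)                       # complete-data FDK reference
res <- run_afn_pipeline(cfg, arc_deg = 270,     # emulate, train, splice,
                        n_trunc_cols = 32,      # FDK-M (post-conv offset wt)
                        ref = ref)
bl  <- run_baselines(cfg, 270, 32, ref = ref)   # the failing classical FDKs
run_sufficiency_sweep(cfg, ref = ref)           # 9-cell rate table
```

`scripts/acceptance.R` runs exactly this plus the analytic checks and writes
every headline number to JSON.
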