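# cbctafn

Cone-beam CT reconstruction for a **simultaneous short-scan and
offset-detector acquisition**, with a per-scan self-supervised **attenuation
field network (AFN)** that inpaints the doubly incomplete sinogram.

## The problem

Dedicated (upright) breast CT would rotate the source over less than 360°
(short scan) while using a flat-panel detector shifted laterally out of the
fan center (offset detector). Fan-beam data are two-fold redundant,

    f(β, γ) = f(β + π + 2γ, −γ),

so either incompleteness alone is fixed by a redundancy weight with unit
pair sums, `w(β, γ) + w(β + π + 2γ, −γ) = 1`: Parker-type weights for the
short scan, an S-shaped column weight for the offset detector. With *both*
at once, some rays have no acquired complement and weighted FDK fails.

The AFN approach trains, per scan, a coordinate-based attenuation function
`h_Θ(r)` (multiresolution hash-grid encoding → 3×64 ReLU MLP → exponential
output) by minimizing the squared error between its rendered line integrals

    p̂(d) = Σᵢ h_Θ(tᵢ) |tᵢ₊₁ − tᵢ|,   tᵢ on the ray source→pixel,

and the acquired projections `p(d) = −ln(I/I₀)` over the acquired set only.
The trained field synthesizes the missing sinogram pixels; splicing them
with the acquired data yields complete projections that any analytic method
can reconstruct — here FDK with the offset-detector weight applied
post-convolution (FDK-M).

The package provides the full chain on synthetic digital breast phantoms:
geometry and acquisition emulation, ray-marching forward projector,
weighted FDK, the AFN (compiled fused training kernels, Adam, deterministic
seeding), image-quality metrics (noise variance, SDNR, calcification FWHM)
with the Shapiro–Wilk-gated paired t/Wilcoxon comparison, and an end-to-end
pipeline with a data-sufficiency sweep.

## Worked example

```r
library(cbctafn)

cfg <- desk_experiment(master_seed = 1)  # desk-scale clinical geometry
ref <- run_reference(cfg)                # phantom -> full scan -> FDK
res <- run_afn_pipeline(cfg, arc_deg = 270, n_trunc_cols = 32, ref = ref)
bl  <- run_baselines(cfg, 270, 32, ref = ref)

res$metrics$rmse_vs_reference            # 0.00568 1/cm
res$metrics$reference_rmse_vs_truth      # 0.00903 1/cm
```

The emulation keeps a 270° arc (45 of 60 views) and removes a quarter of
the detector columns, a 56.25% sampling rate. After 30 training epochs the
AFN loss is below 0.001% of its initial value, and the FDK-M reconstruction
of the spliced sinogram sits at an interior RMSE of 0.0057 cm⁻¹ from the
complete-data reference — *closer to the reference than the reference is to
the ground-truth phantom* (0.0090 cm⁻¹). The classical baselines on the same
incomplete data are an order of magnitude worse:

| reconstruction                  | interior RMSE vs reference (1/cm) |
|---------------------------------|----------------------------------:|
| AFN inpainting + FDK-M          | 0.0057 |
| FDK, Parker weight (zero-fill)  | 0.0349 |
| FDK, offset weight (zero-fill)  | 0.0603 |
| FDK, both weights               | 0.1078 |

and the sufficiency sweep reproduces the analytic sampling rates, e.g.
65.6% for (270°, 2.5 cm offset) and 35.4% for (204°, 7.5 cm) on a 40 cm
panel:

```r
run_sufficiency_sweep(cfg, ref = ref)
```

A thin CLI over the same functions lives in `inst/cli/cbct.R`
(`reference`, `afn`, `baselines`, `sweep` subcommands).

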