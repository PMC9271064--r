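# prolifmap

Biophysical mapping of breast tumor proliferation from serial MRI during
neoadjuvant therapy (NAT).

Conventional MRI response metrics — change in tumor longest dimension, mean
apparent diffusion coefficient (ADC), functional tumor volume (FTV) —
describe morphology, not kinetics. `prolifmap` interprets serial
diffusion-weighted (DW) and dynamic contrast-enhanced (DCE) MR images
through a mechanically coupled reaction–diffusion model of tumor growth and
estimates, between each pair of imaging time points, a spatial map of the
net tumor cell proliferation rate *k(x)* (day⁻¹; negative under effective
therapy) together with a global cell diffusion *D₀* (mm²/day). Histogram
summaries of the proliferation maps are then correlated with residual
cancer burden (RCB), the continuous post-surgical pathology index of
remaining disease.

The model, per 2D central tumor slice:

* cellularity from ADC:
  *N(x,t) = θ · (ADC_w − ADC(x,t)) / (ADC_w − ADC_min)*,
  with θ the voxel carrying capacity (close packing of 10 μm cells),
  ADC_w = 3×10⁻³ mm²/s (free water at 37 °C) and ADC_min the densest tumor
  voxel;
* growth: *∂N/∂t = ∇·(D∇N) + k(x) N (1 − N/θ)*;
* stress damping: *D = D₀ e^(−γ σ_vm)* with σ_vm the von Mises stress;
* quasi-static plane-strain elasticity driven by the cell gradient:
  *∇·(G∇u) + ∇(G/(1−2ν) ∇·u) − λ∇N = 0*, G = E/2(1+ν), ν = 0.45.

The inverse problem (regional *k* on a k-means partition of a 1.5 mm
triangular finite-element mesh, ~5 elements per region, Δt = 1 day) is
solved by bound-constrained L-BFGS-B with adjoint-state gradients for *k*
and a 1% forward-difference gradient for *D₀*.

Patient imaging of the kind this pipeline targets is not redistributable,
so the package ships a synthetic-data module (`make_phantom()`,
`simulate_cellularity_series()`, `render_images()`, `make_cohort()`) that
generates the full study — phantom anatomy, ground-truth kinetics,
forward-simulated cellularity, noisy DW/DCE images at the trial schedule
{0, 29, 96, 172} days, and RCB outcomes tied to the simulated residual
burden — making every stage testable end to end.

## Worked example

Generate a solidly enhancing 8 mm lesion with quadrant ground-truth rates
{−0.10, −0.04, +0.02, −0.06}/day, image it at baseline and day 29 at a b=0
SNR of 20, and recover the proliferation map from the images alone:

```r
library(prolifmap)

phantom <- make_phantom(
  grid_shape = c(48, 48), pixel_spacing = c(1, 1),
  tumor_spec = list(radius_mm = 8, profile = "plateau"),
  k_field_spec = list(mode = "quadrants", values = c(-0.10, -0.04, 0.02, -0.06)),
  D0 = 1e-3)
series <- simulate_cellularity_series(phantom, schedule = c(0, 29))
study  <- render_images(series, noise_sigma = 50, seed = 1)
study
#> <imaging_study> 2 time points (days 0, 29), b = {0, 100, 600, 800} s/mm^2, SNR 20

# imaging -> ADC -> enhancement ROI -> cellularity (cell fraction of theta)
theta <- carrying_capacity(study$spacing, study$slice_thickness)$theta   # 176781
seed_mask <- dilate_mask(phantom$roi_mask, study$spacing, 5) & phantom$domain_mask
frac <- lapply(1:2, function(t) {
  adc   <- compute_adc(study$dw[[t]], study$b_values, b_select = 800)
  roi   <- segment_tumor(study$dce_pre[[t]], study$dce_post[[t]], seed_mask)
  cells <- cellularity_from_adc(adc, roi, theta)
  f <- cells$values / theta; f[is.na(f)] <- 0
  pmin(pmax(f, 0), 1)
})

# FEM mesh + regional partition + fit
mesh <- series$mesh
mesh
#> <tri_mesh> 673 nodes, 1232 triangles, mean edge 1.458 mm, 248 ROI elements
partition <- partition_regions(mesh, elements_per_region = 5)
pair <- observation_pair(raster_to_nodal(frac[[1]], mesh),
                         raster_to_nodal(frac[[2]], mesh),
                         interval_days = 29, pair_label = "T01")
fit <- estimate_proliferation(pair, mesh, partition,
                              model_params(D0 = 1e-3, theta = theta))
fit
#> <prolif_fit> T01: 50 regions, k in [-0.252, 0.541] /day, D0 = 0.02118 mm^2/day,
#>              J = 0.82 (converged, 117 evals)

proliferation_histogram(fit, partition, mesh)
#> <hist_summary> mean -0.0364, median -0.0620, p25 -0.0991, p75 -0.0072,
#>                IQR 0.0918, sd 0.1319 /day
```

The area-weighted histogram mean of −0.036/day recovers the lesion's mixed
response (true area-weighted mean −0.045/day): three quadrants with net cell
death and one with residual proliferation, read off two noisy images 29 days
apart. `tidy(fit)` gives the per-region rates, `plot_proliferation_map(fit,
mesh)` the spatial map, and `autoplot()` the histogram. Rates in regions
whose signal has decayed below the enhancement-detection limit are reported
at their initialization and are not individually identifiable (see the
methods vignette).

A full cohort analysis — six simulated patients, pairs T01/T12/T02, all six
histogram metrics plus the three conventional metrics, Pearson r/p tables
against total and in-breast RCB with significance stars — is one call:

```r
result <- run_pipeline(default_config())
result$report          # r table and starred p table
tidy(result)           # per-patient metric x outcome tibble
plot_cohort_correlations(result)
```

`inst/scripts/prolifmap-cli.R` wraps the same pipeline for shell use
(`simulate`, `fit`, `metrics`, `correlate`, `all` subcommands with
`--config`, `--seed`, `--outdir`).

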