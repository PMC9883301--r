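# cryosims

Analysis of three-dimensional cryo-ToF–SIMS images of hydrated bacterial
biofilms exposed to the antibiotic ciprofloxacin.

Dual-beam ToF–SIMS alternates an imaging ion beam with a sputter beam,
yielding a peak-picked count cube — (layer, row, col, peak) — of a
frozen-hydrated *B. subtilis* biofilm. From such cubes this package:

* extracts sputter **depth profiles**, labels the aqueous / biofilm /
  substrate regions automatically, and calibrates the ciprofloxacin
  (M+H)⁺ / H₂₅O₁₂⁺ intensity ratio against exposure concentration by
  ordinary least squares;
* factorises the images by **MCR-ALS** (non-negative multivariate curve
  resolution, `X ≈ C S` with exact active-set NNLS half-steps and a
  deterministic purest-variable start), and maps factors to semantic roles
  (water, live cells via retained K⁺/Na⁺/Ca⁺, inactive-cell organics,
  Al⁺ substrate);
* **segments** voxels into live cells, inactive cells, aqueous medium and
  substrate by k-means on the MCR scores, labels individual cells as 3-D
  connected components, and reports per-layer cell counts, percent live,
  and the mean cell thickness in sputter cycles;
* **denoises** the cube by noise-whitened low-rank reconstruction (MSF:
  Poisson-variance whitening + truncated SVD, k = 10) and validates it per
  peak with a lack-of-fit statistic *F*ⱼ < 0.99, a layer-mean correlation
  *R*ⱼ² > 0.99, and per-class mean deviations ≤ 10%;
* **quantifies** the antibiotic per compartment on raw counts — the
  (M+H)⁺ / H₃₇O₁₈⁺ ratio per class — with Fisher's exact tests on
  per-voxel detection;
* ships a **synthetic biofilm generator** with complete ground truth
  (layered geometry, 8-layer ellipsoidal cells, water-cluster-dominated
  spectra, Poisson noise, compartment-dependent antibiotic enhancement),
  so the whole pipeline is testable without instrument data.

Interoperability: a versioned binary cube container, a documented
fixed-width event-stream format (reader parameterised by layout), peak
lists as TSV, and processed-mode imzML export.

## Worked example

One call simulates the reference study cube (24 layers × 128 × 128 pixels,
200 peaks, 50 µg/ml exposure) and runs every stage:

```r
library(cryosims)
res <- run_pipeline(pipeline_config(), seed = 1)

glance(res$segmentation)
#> # A tibble: 1 × 4
#>   n_instances n_live pct_live mean_cell_z_extent
#>         <int>  <int>    <dbl>              <dbl>
#> 1         150     54       36                  8

res$quant
#> # A tibble: 4 × 5
#>   class     n_voxels num_counts den_counts   ratio
#>   <chr>        <int>      <int>      <int>   <dbl>
#> 1 live          2690       1147      35977 0.0319
#> 2 inactive      4900        950      65244 0.0146
#> 3 all_cells     7590       2097     101221 0.0207
#> 4 media       336474      51890    7476578 0.00694

res$validation
#> <denoise_validation> 1 peaks; max F_j = 0.0003; min R_j2 = 0.9963
#>   max class deviation = 0.00526
```

Reading the output: 150 cell instances were segmented, 36% of them live
(K⁺-retaining), each spanning on average 8 sputter cycles — one cell
layer. The raw-count antibiotic ratio is highest in live cells (0.032),
intermediate in inactive cells (0.015) and lowest in the medium (0.0069),
i.e. ciprofloxacin penetrates the biofilm and binds preferentially to live
cells. The denoised antibiotic image shows no lack of fit (*F*ⱼ ≈ 0.0003),
tracks the raw depth profile (*R*ⱼ² = 0.996), and preserves every class
mean within 0.6%.

The calibration line from the published depth-profile ratios:

```r
ref <- dplyr::filter(depth_ratio_reference(), region == "aqueous")
fit <- calibration_fit(ref$concentration, ref$ratio)
glance(fit)
#> # A tibble: 1 × 4
#>   r.squared    slope intercept     n
#>       <dbl>    <dbl>     <dbl> <int>
#> 1     1.00  0.000105   0.00543     4
```

`r.squared` is 0.9996 (≥ 0.999) with a strictly positive intercept — the
metastable water-cluster background leaves a nonzero signal at m/z 332.14
even with no antibiotic present.

Each result type has `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures (depth profiles with region shading,
factor spectra, per-layer cell counts, single-layer ion images).

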