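---
title: "Methods: 3D cryo-ToF-SIMS biofilm analysis with cryosims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D cryo-ToF-SIMS biofilm analysis with cryosims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryosims)
```

## The measurement and the analysis problem

Dual-beam time-of-flight secondary ion mass spectrometry (ToF-SIMS) of a
frozen-hydrated biofilm alternates an imaging analysis beam with a sputter
beam, producing a stack of mass-spectral images: one full spectrum per pixel
per sputter cycle. After peak picking, the data form a 4-D count cube
indexed (layer, row, col, peak). The z axis is in sputter cycles — the
sputter yield of ice is unknown, so depth is expressed in "cell layers"
(about 8 cycles erode one bacterium). Layer 1 is the outermost, first-
acquired surface; the biofilm base and the aluminium substrate sit at the
highest layer indices.

Spectra of frozen-hydrated samples are dominated by protonated water
clusters $H_{2n+1}O_n^+$. Cells contribute organic fragments of cell-wall
amino acids, nucleobases and lipid head groups; cells that maintained
potassium homeostasis until cryofixation ("live" cells) additionally retain
K^+^, Na^+^ and Ca^+^. The antibiotic ciprofloxacin appears label-free as
its protonated molecular ion (M+H)^+^ at m/z 332.14 — typically well below
one count per voxel, against a nonzero background caused by metastable
decay of large water clusters in flight.

The analysis chain implemented here answers three questions: where does the
biofilm sit in depth and how much antibiotic is in it (depth profiles and
ratio calibration); which voxels are live cells, inactive cells, aqueous
medium or substrate (MCR-ALS + clustering); and how much antibiotic is
bound in each compartment, quantified on raw counts with denoised images
used only for visualisation and validated per peak (MSF denoising).

## Intensity ratios and calibration

Absolute count rates drift between measurements, so antibiotic intensity is
always reported as a ratio to a large water cluster: $H_{25}O_{12}^+$ for
the low-resolution depth profiles, $H_{37}O_{18}^+$ for the 3-D images.
`region_ratio()` sums the numerator and denominator counts over the layers
of a region and divides the sums (never averaging per-layer ratios, which
would be unstable at low counts). `calibration_fit()` is ordinary least
squares of the aqueous-layer ratio on the exposure concentration; on the
published depth-profile table this line has $R^2 = 0.9996$ and a strictly
positive intercept — the metastable background does not vanish at zero
concentration.

Region labelling (`label_regions()`) is automatic: the biofilm begins where
the summed, max-normalized organic marker signal (m/z 70.07, 44.05, 84.08)
first exceeds 10% of its maximum, the substrate where Al^+^ does likewise,
and one layer on each side of every boundary is excluded as `interface`.
The original analysis shaded these regions manually; an automatic rule was
chosen so results are reproducible, and reports flag it as a stand-in.
The rule is invariant to rescaling and idempotent.

## MCR-ALS

`fit_mcr()` factorises the unfolded cube $X$ (voxels x peaks) as
$X \approx C S$ with $C \ge 0$ (scores) and $S \ge 0$ (factor spectra),
by alternating least squares. Each half-step is an *exact* non-negative
least-squares solve, implemented as a fast combinatorial active-set method
(columns sharing a passive set are solved together; an exhaustive
enumeration over passive sets serves as the cross-check oracle in the test
suite and as a fallback). Exact half-steps make the objective provably
non-increasing, which the fit asserts at every iteration; clipping-based
updates do not have this property, which is why they were not used.

Choices that matter:

* `k = 6` by default: water, live cells, inactive-cell organics,
  substrate, plus two spare factors that absorb ice-spectrum variation
  (detector dead-time nonlinearity) and background. The commercial software
  used in the original analysis does not document its factor count; 6 is
  config-exposed.
* Initialisation is a SIMPLISMA-style purest-variable selection —
  deterministic, so fits are bit-reproducible. Random initialisation is
  retained for robustness checks.
* `weighting = "poisson"` (the pipeline default) scales the matrix by
  row-sum^−1/2^ and column-mean^−1/2^ before fitting. Without it the
  enormous water channels dominate the least-squares objective and the
  cell-type factors degenerate into near-copies of the water spectrum; with
  it the live/inactive organic distinction is recovered reliably. The
  plain unweighted criterion remains the `fit_mcr()` default for
  methodological transparency.
* `tol = 1e-6` relative change in lack of fit, `max_iter = 200`.
* On cubes larger than `subsample` voxels (pipeline default 60,000) the
  iterations run on an evenly strided voxel subset and the final scores are
  computed for all voxels in one exact solve against the converged spectra.
  The stride touches no random numbers, so determinism is preserved; on the
  reference grid the spectra agree with a full fit to within cosine
  similarity > 0.999 while cutting the runtime several-fold.

Factor spectra are normalized to unit maximum after convergence (scores
absorb the scale), which fixes the scale indeterminacy without changing the
reconstruction. Rotational ambiguity is not otherwise constrained; factor
identity is established by marker channels, not claimed from the
factorization itself.

`assign_factors()` maps factors to semantic roles by the share of marker
channels in each spectrum, greedily in the order substrate (Al^+^), live
marker (K^+^/Na^+^/Ca^+^), cell organics (the characteristic fragment
list), water (the cluster series); remaining factors are `other`. The
greedy order resolves the overlap between the two cell-type factors: both
carry organics, only one carries the salts.

## Segmentation

`cluster_voxels()` runs k-means on unit-sum-normalized score vectors
(compositions), because absolute score magnitude is dominated by total ion
yield rather than compartment identity. Seeding is a deterministic
farthest-point traversal plus four random restarts (seeded); the best
within-cluster sum of squares wins. Six clusters by default — more clusters
than classes, since water typically splits into several clusters that all
map to `aqueous`.

`semantic_map()` assigns each cluster the class of the factor in which its
mean score is most *enriched* relative to that factor's global mean score.
Raw dominance would label every cluster `aqueous` (water scores are large
everywhere); enrichment identifies the minority compartments. Ties and
clusters dominated by `other` factors fall back conservatively to
`aqueous`, and a segmentation without any aqueous cluster is rejected as
implausible for these images.

Cell instances are 26-connected components of the cell-class voxels
(`label_cells()`), with components under 4 voxels discarded as specks.
Per-layer cell counts use 2-D 8-connected components within each layer —
matching how cells are counted on single sputter-cycle images — while the
3-D instances provide the z-extent statistic. On the default synthetic
cube the mean instance z extent is 8 layers, the cell thickness in sputter
cycles.

## MSF denoising and its validation

The denoiser (`fit_msf()`/`denoise()`) whitens each peak column by its
noise standard deviation, mean-centers, and projects onto the top-`k`
(default 10) eigenvectors of the whitened covariance; reconstruction
un-centers, un-whitens and clips negatives (the clip-induced mean bias is
reported). Two noise estimators are provided: `poisson_diag` (variance =
column mean, the Poisson identity) and `shift_difference` (half the mean
squared one-layer z-difference, which needs no distributional assumption
but charges sharp z-structure to noise — the test suite shows it inflating
the Al^+^ channel). The exact formulation of the original denoiser is not
public; this module commits to diagonal noise whitening plus truncated SVD,
which reproduces the published validation behaviour, and says so here
rather than claiming equivalence.

Retaining components by count alone has a sharp edge on strongly clustered
count data: the centered class structure of a four-compartment cube spans
only three directions, so with `k = 10` the remaining seven retained
components sit at eigenvalues just above 1. They are not featureless —
diagonal whitening equalizes noise per *channel*, not per voxel, so inside
cells the organic/salt/antibiotic channels carry several-fold more Poisson
variance than their global column means suggest, and the near-unit
components lock onto exactly that cell-localised noise. Projected back,
their chance loadings on the antibiotic channel perturb the cell-class
means. `denoise(shrink = TRUE)` — the pipeline default — therefore weights
each retained component by its signal share $(\lambda - 1)/\lambda$: in
the whitened metric noise contributes unit variance per direction, so this
is the fraction of the component's variance that is signal. Strong
components pass essentially unchanged ($\lambda = 88 \to 0.989$), near-unit
components are suppressed ($\lambda = 1.05 \to 0.05$), and the per-class
mean deviations drop from seed-dependent values of up to ~20% to well
under 1% while $F_j$ and $R_j^2$ keep their contracts. With
`shrink = FALSE` (the `denoise()` default) the operator is a plain
projection and reproduces the input exactly at `k = n_peaks`.

Three per-peak validation statistics certify the result
(`validate_denoise()`):

* $F_j$: residual mean square over noise variance, referred to the CDF of
  an $F(n-k, \infty)$ distribution (Poisson variance treated as known).
  $F_j < 0.99$ reads "no lack of fit at the 1% level"; the threshold is
  config-exposed. On pure-noise simulations about 1% of peaks exceed it,
  as they should.
* $R_j^2$: squared Pearson correlation between layer-by-layer means of
  denoised and raw signal, required > 0.99 for the antibiotic channel.
* Per-class relative deviation of the denoised mean from the raw mean,
  required ≤ 10% for each segmented class volume. Classes whose raw totals
  are under 100 counts are reported but excluded from the pass/fail
  verdict: below that the raw mean itself carries more than ~10% Poisson
  error and the contract is not measurable.

An under-fitted denoiser (k = 1) violates at least one contract on a
four-compartment cube, which is what gives the validation its power.

## Quantification

Compartment ratios (`compartment_ratio()`) are computed on **raw** counts —
denoised images never feed quantification, only display. Significance uses
Fisher's exact test on per-voxel detection (≥ 1 count at m/z 332.14)
between compartments. The original report does not state what its exact
tests were applied to; dichotomised detection is this package's documented
operationalisation — the natural categorical reduction of images whose
analyte channel is mostly 0 or 1 counts. The two-sided p-value is the
point-probability sum, verified against brute-force hypergeometric
enumeration for all tables with n ≤ 30.

## The synthetic generator

`simulate_biofilm()` renders the study conditions with full ground truth:

* Grid 24 layers x 128 x 128 pixels at 0.78 µm/pixel — the published
  100 x 100 µm field at a quarter of the pixel density, for desk-scale
  runtimes.
* Peak list of 200 channels: water clusters n = 1..20 (exponential decay
  $A e^{-\beta n}$, A = 2000 counts, β = 0.25), the 12 characteristic
  organic ions, K^+^/Na^+^/Ca^+^, Al^+^, the (M+H)^+^ channel, and 163
  low-level background channels emulating the long tail of an automated
  peak search (1090 peaks on the real data).
* 150 ellipsoidal cells (rod length 3–5 px, 8-layer z extent via
  half-layer centring), 36% live, placed by rejection sampling with a
  one-voxel separation gap; expected density constant over the basal third
  and decaying toward the surface (dense base, thin pillars). The absolute
  count scale is not printed in the source study; A = 2000 makes the
  antibiotic channel mean ≪ 1 count/voxel at near-MIC exposure, matching
  the described sparsity.
* Cells carry 60% of the aqueous water signal; live and inactive templates
  are identical at the organic channels and differ only in the salts.
* Compartment antibiotic levels come directly from the published
  compartment ratio table: the aqueous baseline is the media column and the
  live/inactive enhancements are the live/media and inactive/media column
  ratios at the chosen concentration. At zero concentration the channel
  carries a uniform metastable floor, flat in z; because cells contain less
  water, their measured *ratio* is then higher than the medium's — the same
  pattern the published zero-concentration row shows.
* Poisson counting noise throughout; optional detector dead-time
  attenuation $I e^{-\tau I}$ on the water channels and an optional
  uniform metastable floor are off by default and exercised in dedicated
  tests.

What the generator does *not* emulate: sputtering physics and redeposition,
matrix effects (beyond the fixed compartment enhancements), profile-mode
mass spectra, EPS-matrix channels (none were identified in the source
data), topography, and cell crowding with touching cells — instances are
gap-separated, so connected-component counting is exact on truth. Passing
tests therefore demonstrate correctness of the algorithms under the stated
noise model, not robustness to every instrumental artefact of real data.

```{r example, eval = FALSE}
sim <- simulate_biofilm(concentration = 50, seed = 1)
res <- run_pipeline(pipeline_config(), seed = 1)
glance(res$segmentation)
res$quant
```

## Problem sizes and determinism

The reference conditions (24 x 128 x 128, 200 peaks, 150 cells) run the
full pipeline in about 1.5 minutes; the unit-test suite works on
16 x 40 x 40 cubes with ~50 peaks, sizes chosen so each module is exercised
in seconds while retaining all four compartments. A single global seed
derives per-stage seeds by hashing the stage name (`derive_seed()`), so any
stage can be re-run in isolation with the stream it would see in the full
pipeline, and identical configuration + seed gives byte-identical report
bundles.

## Known limitations

* The z axis stays uncalibrated (cycles, not µm); no sputter-yield model.
* MCR rotational-ambiguity bands are not computed; factor identity rests
  on marker channels.
* Per-layer cell counting by 2-D components over-counts cells whose
  lateral section pinches into two components in a noisy layer, and the
  2x2x8-voxel minimum makes sub-cell fragments invisible.
* The Fisher detection test discards count magnitude; at saturating
  exposure (every voxel ≥ 1 count) it loses its power by construction and
  the detection fractions are reported alongside.
* The event-stream reader implements this package's documented fixed-width
  layout, parameterised so other dialects can be described, but no vendor
  byte layout is re-implemented.
* imzML export encodes the layer axis as stacked pixel planes and is
  therefore lossy for readers unaware of the convention; the native
  container is the storage format.
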