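Package: cryosims
Title: 3D Cryo-ToF-SIMS Biofilm Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for three-dimensional cryogenic time-of-flight
    secondary ion mass spectrometry (ToF-SIMS) images of hydrated bacterial
    biofilms exposed to the antibiotic ciprofloxacin. Provides peak-picked
    ion-image cube containers with event-stream and imzML interoperability,
    automated peak search on summed spectra, sputter depth-profile region
    labelling and linear calibration of antibiotic-to-water-cluster intensity
    ratios, non-negative multivariate curve resolution by alternating least
    squares (MCR-ALS), noise-whitened low-rank denoising of Poisson count
    images with per-peak lack-of-fit validation, voxel segmentation into
    live cells, inactive cells, aqueous medium and substrate with per-layer
    cell statistics, and compartment-wise antibiotic quantification with
    Fisher's exact detection tests. A synthetic biofilm image generator with
    full ground truth makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
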