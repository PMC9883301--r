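# Published reference values used as inputs: the depth-profile intensity
# ratios and the compartment-wise normalized ciprofloxacin intensities at
# each exposure concentration. These tables parameterise the synthetic
# generator (compartment enhancement factors) and feed the calibration fit.

#' Depth-profile ciprofloxacin-to-water intensity ratios
#'
#' The (M+H)+ to H25O12+ intensity ratios measured in low-lateral-resolution
#' depth profiles, by exposure concentration and region, with replicate
#' standard deviations (three profiles per concentration).
#'
#' @return A tibble with columns `concentration` (ug/ml), `region`
#'   (`aqueous` / `biofilm`), `ratio`, `sd`.
#' @export
depth_ratio_reference <- function() {
  tibble::tribble(
    ~concentration, ~region, ~ratio, ~sd,
    10, "aqueous", 0.0060, 0.0003,
    10, "biofilm", 0.013, 0.003,
    50, "aqueous", 0.012, 0.0004,
    50, "biofilm", 0.022, 0.003,
    100, "aqueous", 0.015, 0.0007,
    100, "biofilm", 0.020, 0.005,
    1000, "aqueous", 0.11, 0.008,
    1000, "biofilm", 0.21, 0.05
  )
}

#' Compartment-wise normalized ciprofloxacin intensities
#'
#' The mean (M+H)+ to H37O18+ count ratios in the high-resolution 3D images,
#' by exposure concentration and segmented compartment. These ratios define
#' the default compartment enhancement factors of the synthetic generator
#' (see [cipro_model()]).
#'
#' @return A tibble with columns `concentration` (ug/ml), `inactive`,
#'   `live`, `all_cells`, `media`.
#' @export
compartment_ratio_reference <- function() {
  tibble::tribble(
    ~concentration, ~inactive, ~live, ~all_cells, ~media,
    1000, 3.3e-1, 6.3e-1, 4.0e-1, 2.2e-1,
    100, 2.1e-2, 3.1e-2, 2.3e-2, 1.3e-2,
    50, 1.4e-2, 3.0e-2, 1.4e-2, 6.9e-3,
    10, 1.1e-2, 1.9e-2, 1.2e-2, 2.9e-3,
    0, 1.9e-3, 3.2e-3, 2.0e-3, 7.4e-4
  )
}
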