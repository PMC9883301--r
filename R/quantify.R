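# Compartment-wise ciprofloxacin quantification on RAW counts (denoised
# images are never used for quantification) and Fisher's exact detection
# tests between compartments.

#' Compartment-wise normalized antibiotic intensity
#'
#' For each voxel class, the ratio of summed ciprofloxacin (M+H)+ counts to
#' summed H37O18+ water-cluster counts over the class volume, computed on
#' raw counts. `all_cells` is the union of live and inactive; substrate is
#' excluded from the report.
#'
#' @param cube_raw Raw (not denoised) [sims_cube()].
#' @param class_map Character (nz, ny, nx) class array aligned with the
#'   cube.
#' @param numerator,denominator Peak labels (defaults `"cipro"`,
#'   `"H37O18+"`).
#' @return A tibble with columns `class` (live, inactive, all_cells,
#'   media), `n_voxels`, `num_counts`, `den_counts`, `ratio` (NA with a
#'   warning when a class denominator is zero or a class is empty).
#' @export
compartment_ratio <- function(cube_raw, class_map, numerator = "cipro",
                              denominator = "H37O18+") {
  stopifnot(inherits(cube_raw, "sims_cube"))
  if (!identical(dim(class_map), dim(cube_raw$counts)[1:3])) {
    abort("class_map geometry does not match the cube")
  }
  num <- peak_channel(cube_raw, numerator)
  den <- peak_channel(cube_raw, denominator)
  groups <- list(live = "live", inactive = "inactive",
                 all_cells = c("live", "inactive"), media = "aqueous")
  purrr::map_dfr(names(groups), function(g) {
    m <- class_map %in% groups[[g]]
    nv <- sum(m)
    ns <- sum(num[m])
    ds <- sum(den[m])
    ratio <- if (nv == 0 || ds <= 0) {
      warn(sprintf("class '%s' empty or zero denominator; ratio undefined", g))
      NA_real_
    } else {
      ns / ds
    }
    tibble::tibble(class = g, n_voxels = nv, num_counts = ns,
                   den_counts = ds, ratio = ratio)
  })
}

#' Per-voxel detection contingency table between two classes
#'
#' Dichotomizes each voxel of two disjoint class volumes by whether it has
#' at least one count at the given peak, yielding the 2x2 table fed to
#' Fisher's exact test. (The exact test needs categorical outcomes;
#' per-voxel detection is the natural categorical reduction of sparse count
#' images.)
#'
#' @param cube_raw Raw [sims_cube()].
#' @param class_map Class array aligned with the cube.
#' @param peak Peak label (default `"cipro"`).
#' @param class_a,class_b Class labels (or vectors of labels) to compare;
#'   must be disjoint.
#' @return A 2x2 integer matrix; rows = class, columns = detected /
#'   not detected. Margins equal the class voxel counts.
#' @export
detection_table <- function(cube_raw, class_map, peak = "cipro",
                            class_a = c("live", "inactive"),
                            class_b = "aqueous") {
  if (length(intersect(class_a, class_b)) > 0) {
    abort("class_a and class_b must be disjoint")
  }
  ch <- peak_channel(cube_raw, peak)
  det <- function(classes) {
    m <- class_map %in% classes
    c(detected = sum(ch[m] >= 1), not_detected = sum(ch[m] < 1))
  }
  tab <- rbind(det(class_a), det(class_b))
  rownames(tab) <- c(paste(class_a, collapse = "+"),
                     paste(class_b, collapse = "+"))
  storage.mode(tab) <- "integer"
  tab
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p by the point-probability method: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' that are no more probable than the observed one. Degenerate tables (a
#' zero column or row margin) are flagged and return p = 1.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return A one-row tibble: `p_value`, `odds_ratio`, `degenerate`.
#' @export
#' @examples
#' fisher_detection(matrix(c(1, 11, 9, 3), 2))
fisher_detection <- function(table) {
  if (!all(dim(table) == c(2, 2))) abort("table must be 2x2")
  if (any(table < 0)) abort("table cells must be non-negative")
  if (any(table != round(table))) abort("table cells must be integers")
  degen <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  ft <- stats::fisher.test(table)
  tibble::tibble(p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 degenerate = degen)
}

#' Write the report bundle
#'
#' Writes tab-separated tables (depth-profile ratios, compartment
#' quantification, per-layer cell statistics, denoise validation) plus a
#' plain-text run manifest with the seed, configuration hash and package
#' version. Outputs are deterministic: identical inputs give byte-identical
#' files. Nonzero diagnostics (dropped events, clipping bias) are included
#' when present.
#'
#' @param out_dir Output directory (created if needed).
#' @param quant Compartment quantification tibble(s) from
#'   [compartment_ratio()]; may carry a `concentration` column.
#' @param validation Optional `denoise_validation`.
#' @param layers Optional layer-statistics tibble.
#' @param profile_ratios Optional depth-profile ratio tibble.
#' @param manifest Named list merged into the manifest (seed, config, ...).
#' @param diagnostics Optional named numeric vector (e.g. dropped events,
#'   max clip bias); written when nonzero.
#' @return Invisibly, the paths written.
#' @export
make_report <- function(out_dir, quant = NULL, validation = NULL,
                        layers = NULL, profile_ratios = NULL,
                        manifest = list(), diagnostics = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    df <- dplyr::select(df, !dplyr::where(is.list))
    write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(quant)) wt(quant, "compartment_ratios.tsv")
  if (!is.null(profile_ratios)) wt(profile_ratios, "depth_profile_ratios.tsv")
  if (!is.null(layers)) wt(layers, "layer_stats.tsv")
  if (!is.null(validation)) {
    wt(validation$peak_stats, "denoise_validation_peaks.tsv")
    if (!is.null(validation$class_stats)) {
      wt(validation$class_stats, "denoise_validation_classes.tsv")
    }
  }
  mf <- c(list(package = "cryosims",
               version = as.character(utils::packageVersion("cryosims"))),
          manifest)
  mf$config_hash <- digest::digest(mf)
  if (!is.null(diagnostics)) {
    nz <- diagnostics[diagnostics != 0]
    if (length(nz)) mf$diagnostics <- as.list(nz)
  }
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(mf, p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
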