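# Pipeline orchestration: one configuration object, one seed, all stages
# in order, everything persisted.

#' Build a pipeline configuration
#'
#' Returns the default configuration, with any provided blocks merged in.
#' Unknown keys are rejected. The configuration round-trips losslessly
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]) and
#' the effective (merged) configuration is written alongside pipeline
#' outputs.
#'
#' @param ... Named blocks overriding defaults, e.g.
#'   `simulate = list(concentration = 1000)`.
#' @return A `pipeline_config` list with blocks `simulate`, `peaksearch`,
#'   `profile`, `mcr`, `denoise`, `segment`, `quantify` and top-level
#'   `seed`, `out_dir`, `verbose`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    verbose = TRUE,
    cube_file = NULL, # analyse an existing container instead of simulating
    simulate = list(
      concentration = 50, grid = c(24L, 128L, 128L), n_cells = 150L,
      live_fraction = 0.36, n_background_peaks = 163L,
      noise = "poisson", metastable_floor = 0, saturation_tau = NULL
    ),
    peaksearch = list(min_prominence = 1e-5, min_separation_mz = 0.05,
                      noise_mult = 3),
    profile = list(threshold_fraction = 0.10,
                   biofilm_markers = c("C4H8N+", "C2H6N+", "C5H10N+"),
                   substrate_marker = "Al+",
                   numerator = "cipro", denominator = "H25O12+"),
    mcr = list(k = 6L, init = "purest_variable", tol = 1e-6,
               max_iter = 200L, weighting = "poisson", subsample = 60000L),
    denoise = list(k = 10L, noise_model = "poisson_diag", shrink = TRUE,
                   f_crit = 0.99, r2_min = 0.99, max_class_deviation = 0.10,
                   min_class_counts = 100L),
    segment = list(n_clusters = 6L, n_restarts = 5L, connectivity = 26L,
                   min_voxels = 4L),
    quantify = list(numerator = "cipro", denominator = "H37O18+")
  )
  user <- list(...)
  merge_config(defaults, user)
}

merge_config <- function(defaults, user, path = "") {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) {
    abort(paste0("unknown configuration key(s): ",
                 paste0(path, bad, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "$"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  structure(defaults, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> peak search -> depth profile -> MCR ->
#' segmentation -> denoising with validation -> quantification, persists
#' every intermediate to `out_dir` when given, and checks the denoising
#' validation contracts for the antibiotic channel (`F_j` below the
#' critical probability, layer-mean `R^2` above the minimum, per-class
#' mean deviation within the tolerance). A single global seed
#' deterministically derives per-stage seeds, so identical configurations
#' give identical bundles.
#'
#' @param config A [pipeline_config()].
#' @param seed Overrides `config$seed` when given.
#' @param out_dir Overrides `config$out_dir` when given.
#' @return A `sims_pipeline_result`: list with `cube`, `truth_class_map`
#'   (NULL for file input), `peaks_found`, `profile`, `profile_ratios`,
#'   `calibration` (NULL unless several concentrations), `mcr`,
#'   `segmentation`, `denoised`, `validation`, `quant`, `fisher`,
#'   `validation_passed` (logical), `failures` (character), `config`.
#'   When validation fails the result is still returned, with
#'   `validation_passed = FALSE`; [stop_on_failure()] converts that into a
#'   hard error for script use.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(out_dir)) config$out_dir <- out_dir
  seed <- config$seed
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # -- simulate or load ------------------------------------------------
  truth_map <- NULL
  if (!is.null(config$cube_file)) {
    say("loading cube from %s", config$cube_file)
    cube <- stage("load", read_cube(config$cube_file))
  } else {
    sc <- config$simulate
    say("simulating synthetic biofilm cube (%g ug/ml, %s)",
        sc$concentration, paste(sc$grid, collapse = "x"))
    sim <- stage("simulate", simulate_biofilm(
      concentration = sc$concentration, grid = sc$grid,
      n_cells = sc$n_cells, live_fraction = sc$live_fraction,
      peaks = default_peaklist(n_background = sc$n_background_peaks),
      noise = sc$noise, metastable_floor = sc$metastable_floor,
      saturation_tau = sc$saturation_tau,
      seed = derive_seed(seed, "simulate")))
    cube <- sim$cube
    truth_map <- sim$class_map
  }
  dims <- dim(cube$counts)[1:3]

  # -- peak search (recovery check on the summed spectrum) -------------
  ps <- config$peaksearch
  say("peak search on the summed spectrum")
  found <- stage("peaksearch", {
    tot <- cube_total_spectrum(cube)
    spec <- tibble::tibble(
      mz = seq(min(tot$center_mz) - 1, max(tot$center_mz) + 1, by = 0.01))
    spec$counts <- 0
    for (i in seq_len(nrow(tot))) {
      j <- which.min(abs(spec$mz - tot$center_mz[i]))
      spec$counts[j] <- spec$counts[j] + tot$counts[i]
    }
    find_peaks(spec, ps$min_prominence, ps$min_separation_mz, ps$noise_mult)
  })

  # -- depth profile ---------------------------------------------------
  prof_cfg <- config$profile
  say("depth profile and region ratios")
  profile <- stage("profile", {
    pr <- extract_profile(cube)
    label_regions(pr, prof_cfg$biofilm_markers, prof_cfg$substrate_marker,
                  prof_cfg$threshold_fraction)
  })
  profile_ratios <- stage("profile", dplyr::bind_rows(
    region_ratio(profile, "aqueous", prof_cfg$numerator, prof_cfg$denominator),
    region_ratio(profile, "biofilm", prof_cfg$numerator, prof_cfg$denominator)
  ))

  # -- MCR -------------------------------------------------------------
  mc <- config$mcr
  say("MCR-ALS factorization (k = %d)", mc$k)
  X <- unfold_cube(cube)$X
  mcr <- stage("mcr", fit_mcr(X, k = mc$k, init = mc$init,
                              seed = derive_seed(seed, "mcr"),
                              tol = mc$tol, max_iter = mc$max_iter,
                              weighting = mc$weighting,
                              subsample = mc$subsample))

  # -- segmentation ----------------------------------------------------
  sg <- config$segment
  say("segmentation (%d clusters)", sg$n_clusters)
  seg <- stage("segment", segment_cube(
    mcr, dims, peaks = cube$peaks, n_clusters = sg$n_clusters,
    seed = derive_seed(seed, "segment"), n_restarts = sg$n_restarts,
    connectivity = sg$connectivity, min_voxels = sg$min_voxels))

  # -- denoise + validate ----------------------------------------------
  dn <- config$denoise
  say("MSF denoising (k = %d) and validation", dn$k)
  msf <- stage("denoise", fit_msf(X, k = dn$k, noise_model = dn$noise_model,
                                  dims = dims))
  Xhat <- stage("denoise", denoise(X, msf, shrink = dn$shrink))
  validation <- stage("denoise", validate_denoise(
    X, Xhat, msf,
    layer_index = rep(seq_len(dims[1]), each = dims[2] * dims[3]),
    class_map = seg$class_map, peaks = "cipro"))
  cst <- validation$class_stats
  fails <- character(0)
  f_j <- validation$peak_stats$F_j[validation$peak_stats$label == "cipro"]
  r_j2 <- validation$peak_stats$R_j2[validation$peak_stats$label == "cipro"]
  # classes whose raw totals are too small to estimate a mean at the 10%
  # level (Poisson relative error > ~10%) are excluded from the pass/fail
  # contract but still reported
  eligible <- cst$label == "cipro" & cst$raw_counts >= dn$min_class_counts
  max_dev <- suppressWarnings(max(cst$deviation[eligible], na.rm = TRUE))
  if (!is.na(f_j) && f_j >= dn$f_crit) {
    fails <- c(fails, sprintf("F_j = %.4f >= %.2f for the antibiotic channel",
                              f_j, dn$f_crit))
  }
  if (!is.na(r_j2) && r_j2 <= dn$r2_min) {
    fails <- c(fails, sprintf("layer-mean R^2 = %.4f <= %.2f", r_j2, dn$r2_min))
  }
  if (is.finite(max_dev) && max_dev > dn$max_class_deviation) {
    fails <- c(fails, sprintf("class mean deviation %.1f%% > %.0f%%",
                              100 * max_dev, 100 * dn$max_class_deviation))
  }

  denoised_cube <- fold_matrix(Xhat, dims, cube$peaks, cube$pixel_size_um,
                               provenance = paste0(cube$provenance,
                                                   " | msf denoised"))
  clip_bias <- attr(Xhat, "clip_bias")
  rm(Xhat, X)
  gc(verbose = FALSE)

  # -- quantify (always on raw counts) ---------------------------------
  qt <- config$quantify
  say("compartment quantification on raw counts")
  quant <- stage("quantify", compartment_ratio(cube, seg$class_map,
                                               qt$numerator, qt$denominator))
  fisher <- stage("quantify", dplyr::bind_rows(
    dplyr::mutate(fisher_detection(detection_table(
      cube, seg$class_map, qt$numerator,
      c("live", "inactive"), "aqueous")), comparison = "all_cells vs media"),
    dplyr::mutate(fisher_detection(detection_table(
      cube, seg$class_map, qt$numerator, "live", "inactive")),
      comparison = "live vs inactive")
  ))

  result <- structure(list(
    cube = cube, truth_class_map = truth_map, peaks_found = found,
    profile = profile, profile_ratios = profile_ratios, mcr = mcr,
    segmentation = seg, denoised = denoised_cube, validation = validation,
    quant = quant, fisher = fisher,
    validation_passed = length(fails) == 0, failures = fails,
    config = config), class = "sims_pipeline_result")

  if (!is.null(config$out_dir)) {
    say("writing report bundle to %s", config$out_dir)
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cube(cube, file.path(config$out_dir, "cube_raw.scube"))
    write_cube(denoised_cube, file.path(config$out_dir, "cube_denoised.scube"))
    write_peaklist(found, file.path(config$out_dir, "peaks_found.tsv"))
    cfg_out <- config
    cfg_out$out_dir <- NULL # bundle content must not depend on its location
    write_pipeline_config(cfg_out, file.path(config$out_dir, "config.yaml"))
    make_report(
      config$out_dir, quant = quant, validation = validation,
      layers = seg$layer_stats, profile_ratios = profile_ratios,
      manifest = list(seed = seed,
                      validation_passed = result$validation_passed,
                      failures = fails,
                      config = unclass(cfg_out)),
      diagnostics = c(dropped_events = attr(cube, "dropped_events") %||% 0,
                      max_clip_bias = max(abs(clip_bias))))
  }
  if (!result$validation_passed) {
    warn(paste0("denoise validation failed: ", paste(fails, collapse = "; ")))
  }
  result
}

#' Error out when a pipeline result failed validation
#'
#' For script use: converts `validation_passed = FALSE` into a hard error
#' (nonzero exit status under `Rscript`), naming the failed contracts.
#'
#' @param result A `sims_pipeline_result`.
#' @return `result`, invisibly, when validation passed.
#' @export
stop_on_failure <- function(result) {
  stopifnot(inherits(result, "sims_pipeline_result"))
  if (!result$validation_passed) {
    abort(paste0("pipeline validation failed: ",
                 paste(result$failures, collapse = "; ")))
  }
  invisible(result)
}

#' @export
print.sims_pipeline_result <- function(x, ...) {
  cat("<sims_pipeline_result>\n")
  print(x$cube)
  cat(sprintf("  validation %s\n",
              if (x$validation_passed) "passed" else
                paste("FAILED:", paste(x$failures, collapse = "; "))))
  invisible(x)
}
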