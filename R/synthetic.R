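# Synthetic frozen-hydrated biofilm image generator.
#
# Forward model, per voxel and peak: the expected count is the compartment
# template mean, plus the ciprofloxacin contribution on the (M+H)+ channel,
# plus an optional uniform metastable background floor; observed counts are
# Poisson. An optional detector dead-time nonlinearity attenuates the
# highest-mean water channels. All geometry, templates, enhancement factors
# and the seed are retained as ground truth so every downstream stage can be
# validated.

#' Build compartment spectral templates
#'
#' Expected mean counts per voxel per analysis cycle for the four
#' compartments (live cell, inactive cell, aqueous medium, substrate).
#' Water cluster means decay exponentially with cluster size,
#' \eqn{A e^{-\beta n}} at the \eqn{H_{2n+1}O_n^+} masses. Both cell types
#' carry the same organic fragment intensities; only live cells carry the
#' K+/Na+/Ca+ viability salts; only the substrate carries Al+. The aqueous
#' template is zero at every organic and salt channel.
#'
#' @param peaks Peak list from [default_peaklist()] (must carry the
#'   `species` column).
#' @param water_amplitude Mean counts of the n = 1 water cluster in the
#'   aqueous compartment (default 2000).
#' @param water_decay Exponential decay rate per cluster size (default
#'   0.25).
#' @param cell_water_fraction Water content of cells relative to the medium
#'   (default 0.6).
#' @param organic_amplitude Mean counts per organic channel in cells
#'   (default 50).
#' @param salt_amplitudes Named vector: mean K+/Na+/Ca+ counts in live
#'   cells.
#' @param substrate_amplitude Mean Al+ counts in substrate voxels (default
#'   500).
#' @param background_level Mean counts of the filler background channels in
#'   water-bearing compartments (default 0.05).
#' @return A `compartment_templates` object: a 4 x n_peaks matrix of means
#'   with rows `live`, `inactive`, `aqueous`, `substrate` and the peak list
#'   attached as attribute `peaks`.
#' @export
build_templates <- function(peaks = default_peaklist(),
                            water_amplitude = 2000,
                            water_decay = 0.25,
                            cell_water_fraction = 0.6,
                            organic_amplitude = 50,
                            salt_amplitudes = c(K = 100, Na = 30, Ca = 10),
                            substrate_amplitude = 500,
                            background_level = 0.05) {
  validate_peaklist(peaks)
  if (!"species" %in% names(peaks)) abort("peak list must carry a species column")
  amps <- c(water_amplitude, organic_amplitude, substrate_amplitude,
            background_level, salt_amplitudes)
  if (any(amps < 0)) abort("template amplitudes must be non-negative")
  np <- nrow(peaks)
  tm <- matrix(0, 4, np, dimnames = list(
    c("live", "inactive", "aqueous", "substrate"), peaks$label))
  wat <- peaks$species == "water"
  n_clust <- as.numeric(sub("^H\\d+O(\\d+)\\+$", "\\1", peaks$label[wat]))
  wmean <- water_amplitude * exp(-water_decay * n_clust)
  tm["aqueous", wat] <- wmean
  tm["live", wat] <- tm["inactive", wat] <- cell_water_fraction * wmean
  org <- peaks$species == "organic"
  tm["live", org] <- tm["inactive", org] <- organic_amplitude
  tm["live", peaks$species == "salt_K"] <- salt_amplitudes[["K"]]
  tm["live", peaks$species == "salt_Na"] <- salt_amplitudes[["Na"]]
  tm["live", peaks$species == "salt_Ca"] <- salt_amplitudes[["Ca"]]
  tm["substrate", peaks$species == "substrate_Al"] <- substrate_amplitude
  bg <- peaks$species == "background"
  tm[c("live", "inactive", "aqueous"), bg] <- background_level
  structure(tm, peaks = peaks, class = c("compartment_templates", "matrix"))
}

#' Ciprofloxacin compartment enhancement model
#'
#' Expected (M+H)+ to H37O18+ count ratio per compartment at a given
#' exposure concentration. Defaults are taken from the published
#' compartment table ([compartment_ratio_reference()]): the aqueous baseline
#' is the media column and the cell enhancements are the live/media and
#' inactive/media column ratios. At zero concentration the (M+H)+ channel
#' carries only the uniform metastable decay background.
#'
#' @param concentration Exposure concentration in ug/ml (0, 10, 50, 100 or
#'   1000 use the published rows; other values interpolate linearly on the
#'   media baseline).
#' @param reference Reference table shaped like
#'   [compartment_ratio_reference()].
#' @param background_ratio_at_zero Metastable background expressed as an
#'   aqueous-equivalent ratio at zero concentration (default: the
#'   zero-concentration media entry, 7.4e-4).
#' @return A `cipro_model` list with fields `concentration`,
#'   `baseline_ratio_aqueous`, `enhancement_inactive`, `enhancement_live`,
#'   `background_ratio_at_zero`.
#' @export
cipro_model <- function(concentration,
                        reference = compartment_ratio_reference(),
                        background_ratio_at_zero = NULL) {
  stopifnot(is_scalar_number(concentration), concentration >= 0)
  bg <- background_ratio_at_zero %||%
    reference$media[reference$concentration == 0]
  if (length(bg) == 0) bg <- 7.4e-4
  if (bg <= 0) abort("background_ratio_at_zero must be > 0")
  pos <- reference[reference$concentration > 0, ]
  row <- reference[reference$concentration == concentration, ]
  if (nrow(row) == 1 && concentration > 0) {
    baseline <- row$media
    enh_i <- row$inactive / row$media
    enh_l <- row$live / row$media
  } else if (concentration == 0) {
    baseline <- bg
    enh_i <- enh_l <- 1
  } else {
    baseline <- stats::approx(pos$concentration, pos$media,
                              xout = concentration, rule = 2)$y
    enh_i <- mean(pos$inactive / pos$media)
    enh_l <- mean(pos$live / pos$media)
  }
  if (enh_l < enh_i || enh_i < 1) {
    abort("cipro model requires enhancement_live >= enhancement_inactive >= 1")
  }
  structure(list(concentration = concentration,
                 baseline_ratio_aqueous = baseline,
                 enhancement_inactive = enh_i,
                 enhancement_live = enh_l,
                 background_ratio_at_zero = bg),
            class = "cipro_model")
}

#' Place cells in the synthetic biofilm volume
#'
#' Cells are axis-aligned ellipsoids (rod-shaped laterally, spanning eight
#' sputter layers in depth by default) placed by rejection sampling so that
#' no two cells touch. Depth centres follow the layered biofilm geometry:
#' a constant expected density over the basal fraction of the biofilm
#' (dense base) decaying linearly toward the outer surface (thin pillars).
#' Cell viability is assigned by independent Bernoulli draws.
#'
#' @param grid Integer (nz, ny, nx) cube dimensions (default 24 x 128 x
#'   128).
#' @param n_cells Number of cells to place (default 150).
#' @param live_fraction Probability that a cell is live (default 0.36).
#' @param substrate_layers Number of basal substrate layers (default 3).
#' @param surface_clear_layers Cell-free aqueous layers at the outer surface
#'   (default 4).
#' @param basal_fraction Fraction of the biofilm depth (adjacent to the
#'   substrate) with constant cell density (default 1/3).
#' @param surface_density Relative expected density at the outermost biofilm
#'   layer (default 0.15 of basal).
#' @param z_semi_axis Cell semi-axis along z in layers (default 4: an
#'   8-layer z extent with half-layer centring).
#' @param lateral_semi_axes Range of the rod's major lateral semi-axis in
#'   pixels (default c(1.5, 2.5); the minor semi-axis is fixed at 1.5).
#' @param pixel_size_um Lateral pixel size (default 0.78, i.e. a 100 um
#'   field imaged at 128 pixels).
#' @param seed Integer seed; same seed, same truth.
#' @param max_attempts Rejection-sampling budget per cell (default 200);
#'   exceeding it raises a packing-infeasibility error.
#' @return A `biofilm_truth` object: list with `cells` (tibble: id, cx, cy,
#'   cz, ax, ay, az, type), `grid`, `pixel_size_um`, geometry parameters and
#'   `seed`. Templates and the cipro model are attached by
#'   [simulate_biofilm()].
#' @export
place_cells <- function(grid = c(24, 128, 128), n_cells = 150,
                        live_fraction = 0.36, substrate_layers = 3,
                        surface_clear_layers = 4, basal_fraction = 1 / 3,
                        surface_density = 0.15, z_semi_axis = 4,
                        lateral_semi_axes = c(1.5, 2.5),
                        pixel_size_um = 100 / 128, seed = 1,
                        max_attempts = 200) {
  stopifnot(length(grid) == 3, live_fraction >= 0, live_fraction <= 1)
  nz <- grid[1]; ny <- grid[2]; nx <- grid[3]
  # admissible z centres: cell spans layers k - (az - 1) .. k + az around a
  # half-layer centre at k + 0.5
  z_lo <- surface_clear_layers + z_semi_axis     # top-most admissible k
  z_hi <- nz - substrate_layers - z_semi_axis    # deepest admissible k
  if (z_hi < z_lo) abort("grid too shallow for the requested cell geometry")
  zc <- z_lo:z_hi
  # density weight per z centre: constant over the basal block, then linear
  # decay toward the surface
  depth <- (zc - z_lo) / max(z_hi - z_lo, 1) # 0 at surface end, 1 at base
  basal_cut <- 1 - basal_fraction
  w <- ifelse(depth >= basal_cut, 1,
              surface_density + (1 - surface_density) * depth / basal_cut)
  with_seed(seed, {
    cells <- tibble::tibble(id = integer(), cx = numeric(), cy = numeric(),
                            cz = numeric(), ax = numeric(), ay = numeric(),
                            az = numeric(), type = character())
    boxes <- matrix(numeric(0), ncol = 6) # lo/hi per axis, gap-dilated
    for (i in seq_len(n_cells)) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        k <- sample(zc, 1, prob = w)
        czi <- k + 0.5
        major <- runif(1, lateral_semi_axes[1], lateral_semi_axes[2])
        if (runif(1) < 0.5) {
          axi <- major; ayi <- 1.5
        } else {
          axi <- 1.5; ayi <- major
        }
        cxi <- runif(1, axi + 1, nx - axi)
        cyi <- runif(1, ayi + 1, ny - ayi)
        box <- c(czi - z_semi_axis - 1, czi + z_semi_axis + 1,
                 cyi - ayi - 1, cyi + ayi + 1,
                 cxi - axi - 1, cxi + axi + 1)
        clash <- FALSE
        if (nrow(boxes) > 0) {
          clash <- any(box[1] <= boxes[, 2] & box[2] >= boxes[, 1] &
                         box[3] <= boxes[, 4] & box[4] >= boxes[, 3] &
                         box[5] <= boxes[, 6] & box[6] >= boxes[, 5])
        }
        if (!clash) {
          boxes <- rbind(boxes, box)
          cells <- dplyr::bind_rows(cells, tibble::tibble(
            id = i, cx = cxi, cy = cyi, cz = czi,
            ax = axi, ay = ayi, az = z_semi_axis,
            type = if (rbinom(1, 1, live_fraction) == 1) "live" else "inactive"
          ))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(sprintf(
          "cell packing infeasible: placed %d of %d cells within the attempt budget",
          i - 1, n_cells))
      }
    }
    structure(list(cells = cells, grid = grid, pixel_size_um = pixel_size_um,
                   substrate_layers = substrate_layers,
                   surface_clear_layers = surface_clear_layers,
                   live_fraction = live_fraction, seed = seed),
              class = "biofilm_truth")
  })
}

#' Ground-truth compartment map of a placed-cell truth
#'
#' @param truth A `biofilm_truth` from [place_cells()].
#' @return A (nz, ny, nx) character array with values `live`, `inactive`,
#'   `aqueous`, `substrate`. Later-placed cells win voxel overlaps (none
#'   occur under the default gap-enforced placement).
#' @export
truth_class_map <- function(truth) {
  nz <- truth$grid[1]; ny <- truth$grid[2]; nx <- truth$grid[3]
  cm <- array("aqueous", c(nz, ny, nx))
  if (truth$substrate_layers > 0) {
    cm[(nz - truth$substrate_layers + 1):nz, , ] <- "substrate"
  }
  for (i in seq_len(nrow(truth$cells))) {
    cl <- truth$cells[i, ]
    zr <- max(1, ceiling(cl$cz - cl$az)):min(nz, floor(cl$cz + cl$az))
    yr <- max(1, ceiling(cl$cy - cl$ay)):min(ny, floor(cl$cy + cl$ay))
    xr <- max(1, ceiling(cl$cx - cl$ax)):min(nx, floor(cl$cx + cl$ax))
    dz2 <- ((zr - cl$cz) / cl$az)^2
    dy2 <- ((yr - cl$cy) / cl$ay)^2
    dx2 <- ((xr - cl$cx) / cl$ax)^2
    inside <- outer(dz2, outer(dy2, dx2, "+"), "+") <= 1
    sub <- cm[zr, yr, xr, drop = FALSE]
    sub[inside] <- cl$type
    cm[zr, yr, xr] <- sub
  }
  cm
}

#' Render a synthetic truth into an observed ion-image cube
#'
#' Applies the forward model: per-voxel expected spectra from the
#' compartment templates, the ciprofloxacin contribution on the (M+H)+
#' channel (the compartment ratio times the compartment's H37O18+ mean; the
#' uniform metastable floor at zero concentration), an optional uniform
#' metastable floor on all channels, an optional dead-time attenuation
#' \eqn{I e^{-\tau I}} on the water channels, then Poisson sampling.
#'
#' @param truth A `biofilm_truth` (from [place_cells()]) with `templates`
#'   and `cipro` attached, as produced by [simulate_biofilm()]; or pass
#'   `templates` / `cipro` explicitly.
#' @param templates A `compartment_templates` matrix (default: attached to
#'   `truth`, else [build_templates()]).
#' @param cipro A [cipro_model()] (default: attached to `truth`, else 50
#'   ug/ml).
#' @param noise `"poisson"` (default) for counting noise or `"none"` for
#'   the exact analytic expectation (deterministic test hook).
#' @param metastable_floor Uniform background mean added to every channel
#'   (counts; default 0 = off).
#' @param saturation_tau Dead-time constant applied to water channels
#'   (default NULL = off).
#' @param seed Integer seed for the Poisson draw.
#' @return A list with `cube` (a [sims_cube()]), `class_map` (ground-truth
#'   compartment array, same geometry) and `truth`.
#' @export
render_cube <- function(truth, templates = NULL, cipro = NULL,
                        noise = c("poisson", "none"),
                        metastable_floor = 0, saturation_tau = NULL,
                        seed = 1) {
  noise <- match.arg(noise)
  templates <- templates %||% truth$templates %||% build_templates()
  cipro <- cipro %||% truth$cipro %||% cipro_model(50)
  peaks <- attr(templates, "peaks")
  cm <- truth_class_map(truth)
  nz <- truth$grid[1]; ny <- truth$grid[2]; nx <- truth$grid[3]
  np <- nrow(peaks)
  cls <- c("live", "inactive", "aqueous", "substrate")
  class_idx <- array(match(cm, cls), dim(cm))
  # per-compartment expected spectra, cipro channel included
  tm <- unclass(templates)[cls, , drop = FALSE]
  den_i <- peak_index(peaks, paste0("H", 2 * 18 + 1, "O", 18, "+"))
  cip_i <- peak_index(peaks, "cipro")
  wat_aq <- tm["aqueous", den_i]
  if (cipro$concentration > 0) {
    ratio <- c(
      live = cipro$baseline_ratio_aqueous * cipro$enhancement_live,
      inactive = cipro$baseline_ratio_aqueous * cipro$enhancement_inactive,
      aqueous = cipro$baseline_ratio_aqueous,
      substrate = cipro$background_ratio_at_zero
    )
    tm[, cip_i] <- ratio[cls] * tm[, den_i]
    tm["substrate", cip_i] <- cipro$background_ratio_at_zero * wat_aq
  } else {
    # metastable decay background: uniform in space, flat in z
    tm[, cip_i] <- cipro$background_ratio_at_zero * wat_aq
  }
  if (metastable_floor > 0) tm <- tm + metastable_floor
  if (!is.null(saturation_tau)) {
    wat <- which(peaks$species == "water")
    tm[, wat] <- tm[, wat] * exp(-saturation_tau * tm[, wat])
  }
  counts <- array(if (noise == "poisson") 0L else 0, c(nz, ny, nx, np))
  n_vox <- nz * ny * nx
  ci <- as.vector(class_idx)
  with_seed(seed, {
    for (p in seq_len(np)) {
      mu <- tm[, p][ci]
      v <- if (noise == "poisson") rpois(n_vox, mu) else mu
      counts[, , , p] <- v
    }
  })
  cube <- sims_cube(counts, peaks, truth$pixel_size_um,
                    provenance = sprintf(
                      "synthetic biofilm (seed %s, %g ug/ml, noise %s)",
                      format(truth$seed), cipro$concentration, noise))
  list(cube = cube, class_map = cm, truth = truth)
}

#' Simulate a complete synthetic biofilm measurement
#'
#' Convenience wrapper: builds templates, the cipro model and the cell
#' geometry, then renders the observed cube. The defaults are the package's
#' reference study conditions: a 24 x 128 x 128 grid at 0.78 um/pixel, 150
#' gap-separated ellipsoidal cells spanning 8 layers, 36% live fraction, a
#' dense basal third thinning toward the surface, water-dominated spectra
#' with Poisson counting noise, and compartment ciprofloxacin levels taken
#' from the published compartment ratio table.
#'
#' @param concentration Ciprofloxacin exposure in ug/ml (default 50).
#' @param grid Integer (nz, ny, nx) (default c(24, 128, 128)).
#' @param n_cells,live_fraction Passed to [place_cells()].
#' @param peaks Peak list (default [default_peaklist()]).
#' @param noise,metastable_floor,saturation_tau Passed to [render_cube()].
#' @param seed Integer seed governing placement and noise.
#' @param ... Further arguments to [place_cells()] or [build_templates()]
#'   (matched by name).
#' @return A list with `cube`, `class_map`, `truth` (see [render_cube()]).
#' @export
#' @examples
#' sim <- simulate_biofilm(grid = c(12, 24, 24), n_cells = 6,
#'                         peaks = default_peaklist(n_background = 3),
#'                         seed = 7)
#' sim$cube
simulate_biofilm <- function(concentration = 50, grid = c(24, 128, 128),
                             n_cells = 150, live_fraction = 0.36,
                             peaks = default_peaklist(),
                             noise = "poisson", metastable_floor = 0,
                             saturation_tau = NULL, seed = 1, ...) {
  dots <- list(...)
  pc_args <- dots[names(dots) %in% names(formals(place_cells))]
  bt_args <- dots[names(dots) %in% names(formals(build_templates))]
  truth <- do.call(place_cells, c(list(grid = grid, n_cells = n_cells,
                                       live_fraction = live_fraction,
                                       seed = derive_seed(seed, "place")),
                                  pc_args))
  truth$templates <- do.call(build_templates, c(list(peaks = peaks), bt_args))
  truth$cipro <- cipro_model(concentration)
  truth$seed <- seed
  render_cube(truth, noise = noise, metastable_floor = metastable_floor,
              saturation_tau = saturation_tau,
              seed = derive_seed(seed, "render"))
}

#' Profile-mode template spectrum for peak-search validation
#'
#' Renders a continuous summed spectrum from a template: Gaussian peaks of
#' the template's total intensities on a uniform m/z grid, as would be seen
#' in a summed profile-mode spectrum.
#'
#' @param templates A `compartment_templates` matrix.
#' @param weights Named compartment weights (voxel counts per compartment);
#'   default equal weights.
#' @param mz_step Grid spacing (default 0.01 u).
#' @param sigma Gaussian peak width (default 0.012 u).
#' @param mz_range Axis range (default spans the peak list).
#' @return A tibble with columns `mz`, `counts`.
#' @export
template_spectrum <- function(templates, weights = NULL, mz_step = 0.01,
                              sigma = 0.012, mz_range = NULL) {
  peaks <- attr(templates, "peaks")
  w <- weights %||% setNames(rep(1, 4), rownames(templates))
  tot <- as.numeric(w[rownames(templates)] %*% unclass(templates))
  mz_range <- mz_range %||% (range(peaks$center_mz) + c(-1, 1))
  mz <- seq(mz_range[1], mz_range[2], by = mz_step)
  y <- numeric(length(mz))
  for (i in seq_len(nrow(peaks))) {
    if (tot[i] <= 0) next
    lo <- findInterval(peaks$center_mz[i] - 5 * sigma, mz)
    hi <- findInterval(peaks$center_mz[i] + 5 * sigma, mz) + 1
    idx <- max(1, lo):min(length(mz), hi)
    y[idx] <- y[idx] + tot[i] * exp(-(mz[idx] - peaks$center_mz[i])^2 / (2 * sigma^2))
  }
  tibble::tibble(mz = mz, counts = y)
}
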