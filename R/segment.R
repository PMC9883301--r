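# Voxel segmentation: k-means clustering of MCR score vectors, semantic
# mapping of clusters to {live, inactive, aqueous, substrate}, connected-
# component cell instance labelling, and per-layer cell statistics.

#' Cluster voxels on their MCR score vectors
#'
#' k-means on row-normalized (unit-sum) score vectors, seeded by a
#' deterministic farthest-point traversal plus `n_restarts - 1` random
#' restarts; the solution with the smallest within-cluster sum of squares
#' wins. Reproducible given `seed`.
#'
#' @param scores Numeric matrix, voxels x factors (e.g. `model$C`).
#' @param n_clusters Number of clusters (default 6; several clusters may
#'   map to one semantic class).
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Total starts including the deterministic one (default
#'   5).
#' @param iter_max k-means iteration cap (default 50).
#' @return Integer cluster id per voxel; attribute `centers` holds the
#'   cluster centres in normalized-score space, attribute `withinss` the
#'   winning total within-cluster sum of squares.
#' @export
cluster_voxels <- function(scores, n_clusters = 6, seed = 1, n_restarts = 5,
                           iter_max = 50) {
  if (n_clusters < 2) abort("n_clusters must be >= 2")
  rs <- rowSums(scores)
  rs[rs == 0] <- 1
  Z <- scores / rs
  if (nrow(Z) <= 1e5) {
    n_distinct <- nrow(unique(Z))
    if (n_clusters > n_distinct) {
      abort(sprintf("n_clusters = %d exceeds the %d distinct score rows",
                    n_clusters, n_distinct))
    }
  }
  centers <- farthest_point_centers(Z, n_clusters)
  fits <- vector("list", n_restarts)
  fits[[1]] <- suppressWarnings(
    kmeans(Z, centers = centers, iter.max = iter_max))
  if (n_restarts > 1) {
    for (r in 2:n_restarts) {
      fits[[r]] <- with_seed(derive_seed(seed, paste0("kmeans", r)),
                             suppressWarnings(
                               kmeans(Z, centers = n_clusters,
                                      iter.max = iter_max, nstart = 1)))
    }
  }
  best <- fits[[which.min(vapply(fits, function(f) f$tot.withinss, numeric(1)))]]
  out <- best$cluster
  attr(out, "centers") <- best$centers
  attr(out, "withinss") <- best$tot.withinss
  out
}

# Deterministic farthest-point (maximin) seeding: start from the point
# farthest from the data centroid, then repeatedly add the point with the
# largest distance to its nearest chosen centre.
farthest_point_centers <- function(Z, k) {
  mu <- colMeans(Z)
  d2 <- rowSums(sweep(Z, 2, mu)^2)
  sel <- which.max(d2)
  mind <- rowSums(sweep(Z, 2, Z[sel, ])^2)
  while (length(sel) < k) {
    cand <- which.max(mind)
    sel <- c(sel, cand)
    mind <- pmin(mind, rowSums(sweep(Z, 2, Z[cand, ])^2))
  }
  Z[sel, , drop = FALSE]
}

#' Map clusters to semantic voxel classes
#'
#' Each cluster is assigned the semantic role of the factor that dominates
#' its mean score vector, where dominance is measured as enrichment: the
#' cluster's mean score on a factor divided by that factor's global mean
#' score (raw score magnitudes are dominated by the water factor
#' everywhere, so relative enrichment, not absolute score, identifies the
#' minority compartments). Role-to-class mapping: `live_marker` -> live,
#' `cell_organic` -> inactive, `water` -> aqueous, `substrate` ->
#' substrate; clusters dominated by an `other` factor, and ties, fall back
#' conservatively to aqueous.
#'
#' @param clusters Integer cluster ids from [cluster_voxels()].
#' @param model The fitted `mcr_model`.
#' @param roles Role map from [assign_factors()].
#' @return Character vector of classes per voxel (`live`, `inactive`,
#'   `aqueous`, `substrate`); attribute `cluster_class` gives the
#'   cluster-to-class table.
#' @export
semantic_map <- function(clusters, model, roles) {
  stopifnot(inherits(model, "mcr_model"))
  ids <- sort(unique(clusters))
  global_mean <- colMeans(model$C)
  global_mean[global_mean <= 0] <- .Machine$double.eps
  role_of_factor <- roles$role[order(roles$factor)]
  role2class <- c(live_marker = "live", cell_organic = "inactive",
                  water = "aqueous", substrate = "substrate", other = "aqueous")
  cl_class <- vapply(ids, function(id) {
    m <- colMeans(model$C[clusters == id, , drop = FALSE])
    enrich <- m / global_mean
    best <- which(enrich == max(enrich))
    if (length(best) > 1) return("aqueous") # tie -> conservative
    unname(role2class[role_of_factor[best]])
  }, character(1))
  if (!"aqueous" %in% cl_class) {
    abort("no cluster maps to the aqueous medium; segmentation is implausible")
  }
  out <- cl_class[match(clusters, ids)]
  attr(out, "cluster_class") <- tibble::tibble(cluster = ids, class = cl_class)
  out
}

# Connected components of a logical 3-D mask under a voxel connectivity
# (26, 18 or 6 in 3-D; 8 or 4 in 2-D when nz == 1). Returns an integer
# label array (0 = background).
connected_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- neighbour_offsets(connectivity)
  idx <- which(mask)
  if (length(idx) == 0) return(array(0L, d))
  comp_id <- array(0L, d)
  comp_id[idx] <- seq_along(idx)
  coord <- arrayInd(idx, d)
  edges <- list()
  key <- array(0L, d)
  key[idx] <- seq_along(idx)
  for (o in offs) {
    nb <- sweep(coord, 2, o, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1) * d[1] * d[2] + (nb[ok, 2] - 1) * d[1] + nb[ok, 1]
    hit <- key[lin] > 0
    if (any(hit)) {
      edges[[length(edges) + 1]] <- cbind(which(ok)[hit], key[lin][hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)$membership
  lab <- array(0L, d)
  lab[idx] <- comp
  lab
}

# Positive half-space neighbour offsets for the given connectivity.
neighbour_offsets <- function(connectivity) {
  all_offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  all_offs <- all_offs[!(all_offs$dz == 0 & all_offs$dy == 0 & all_offs$dx == 0), ]
  keep <- switch(as.character(connectivity),
    "26" = rep(TRUE, nrow(all_offs)),
    "18" = rowSums(abs(all_offs)) <= 2,
    "6" = rowSums(abs(all_offs)) == 1,
    "8" = all_offs$dz == 0,
    "4" = all_offs$dz == 0 & rowSums(abs(all_offs)) == 1,
    abort("connectivity must be one of 26, 18, 6 (3-D) or 8, 4 (2-D)")
  )
  offs <- all_offs[keep, ]
  # positive half-space only: each unordered pair visited once
  pos <- offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 | (offs$dy == 0 & offs$dx > 0)))
  lapply(which(pos), function(i) as.numeric(offs[i, ]))
}

#' Label individual cells as 3-D connected components
#'
#' Connected components over the union of live and inactive voxels
#' (26-connectivity by default); components smaller than `min_voxels` are
#' discarded as noise; each surviving instance takes the majority class of
#' its voxels.
#'
#' @param class_map Character (nz, ny, nx) array of voxel classes.
#' @param connectivity 26 (default), 18 or 6.
#' @param min_voxels Minimum instance size (default 4).
#' @return A list: `instance_map` (integer array, 0 = none) and `instances`
#'   (tibble: `instance`, `class`, `n_voxels`, `z_min`, `z_max`,
#'   `z_extent`).
#' @export
label_cells <- function(class_map, connectivity = 26, min_voxels = 4) {
  mask <- array(class_map %in% c("live", "inactive"), dim(class_map))
  lab <- connected_components(mask, connectivity)
  if (max(lab) == 0) {
    return(list(instance_map = lab,
                instances = tibble::tibble(instance = integer(),
                                           class = character(),
                                           n_voxels = integer(),
                                           z_min = integer(), z_max = integer(),
                                           z_extent = integer())))
  }
  idx <- which(lab > 0)
  comp <- lab[idx]
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_voxels)
  renum <- integer(length(sizes))
  renum[keep] <- seq_along(keep)
  lab[idx] <- renum[comp]
  idx <- which(lab > 0)
  if (length(idx) == 0) { # every component was a sub-threshold speck
    return(list(instance_map = lab,
                instances = tibble::tibble(instance = integer(),
                                           class = character(),
                                           n_voxels = integer(),
                                           z_min = integer(), z_max = integer(),
                                           z_extent = integer())))
  }
  comp <- lab[idx]
  zc <- arrayInd(idx, dim(class_map))[, 1]
  cls <- class_map[idx]
  inst <- tibble::tibble(instance = comp, z = zc, class = cls) |>
    dplyr::group_by(.data$instance) |>
    dplyr::summarise(
      class = names(which.max(table(.data$class))),
      n_voxels = dplyr::n(),
      z_min = min(.data$z), z_max = max(.data$z),
      z_extent = max(.data$z) - min(.data$z) + 1L,
      .groups = "drop")
  list(instance_map = lab, instances = inst)
}

#' Per-layer cell statistics
#'
#' Cells are counted per layer as 2-D 8-connected components of the cell
#' mask within that layer (matching per-layer counting of cells seen in a
#' single sputter cycle); a layer component is live if the majority of its
#' voxels are live. The mean cell z extent comes from the 3-D instances.
#'
#' @param class_map Character (nz, ny, nx) class array.
#' @param instances Instance tibble from [label_cells()] (for the z-extent
#'   summary); optional.
#' @return A tibble with columns `layer`, `n_cells`, `n_live`, `pct_live`
#'   (NA when a layer has no cells); attribute `mean_cell_z_extent`.
#' @export
layer_stats <- function(class_map, instances = NULL) {
  d <- dim(class_map)
  out <- purrr::map_dfr(seq_len(d[1]), function(z) {
    sl <- array(class_map[z, , ], c(1, d[2], d[3]))
    mask <- array(sl %in% c("live", "inactive"), dim(sl))
    lab <- connected_components(mask, 8)
    n <- max(lab)
    n_live <- 0L
    if (n > 0) {
      for (i in seq_len(n)) {
        cls <- sl[lab == i]
        if (sum(cls == "live") > length(cls) / 2) n_live <- n_live + 1L
      }
    }
    tibble::tibble(layer = z, n_cells = n, n_live = n_live,
                   pct_live = if (n > 0) 100 * n_live / n else NA_real_)
  })
  attr(out, "mean_cell_z_extent") <-
    if (!is.null(instances) && nrow(instances) > 0) {
      mean(instances$z_extent)
    } else {
      NA_real_
    }
  out
}

#' Segment a cube end to end
#'
#' Convenience wrapper: clusters the MCR scores, maps clusters to classes,
#' labels 3-D cell instances and computes per-layer statistics.
#'
#' @param model Fitted `mcr_model` for the cube.
#' @param dims Integer (nz, ny, nx) of the cube.
#' @param peaks Peak list (for factor role markers).
#' @param n_clusters,seed,n_restarts Passed to [cluster_voxels()].
#' @param connectivity,min_voxels Passed to [label_cells()].
#' @return A `sims_segmentation`: list with `class_map` (array),
#'   `instance_map`, `instances`, `layer_stats`, `mean_cell_z_extent`,
#'   `roles`, `cluster_class`.
#' @export
segment_cube <- function(model, dims, peaks = default_peaklist(),
                         n_clusters = 6, seed = 1, n_restarts = 5,
                         connectivity = 26, min_voxels = 4) {
  clusters <- cluster_voxels(model$C, n_clusters, seed = seed,
                             n_restarts = n_restarts)
  roles <- assign_factors(model, peaks)
  cls <- semantic_map(clusters, model, roles)
  class_map <- fold_map(cls, dims)
  cells <- label_cells(class_map, connectivity, min_voxels)
  ls <- layer_stats(class_map, cells$instances)
  structure(list(class_map = class_map, instance_map = cells$instance_map,
                 instances = cells$instances, layer_stats = ls,
                 mean_cell_z_extent = attr(ls, "mean_cell_z_extent"),
                 roles = roles,
                 cluster_class = attr(cls, "cluster_class")),
            class = "sims_segmentation")
}

#' @export
print.sims_segmentation <- function(x, ...) {
  tab <- table(x$class_map)
  cat("<sims_segmentation>", paste(names(tab), as.integer(tab), collapse = ", "),
      "\n")
  cat(sprintf("  %d cell instances; mean z extent %.2f layers\n",
              nrow(x$instances), x$mean_cell_z_extent))
  invisible(x)
}

#' @method tidy sims_segmentation
#' @export
tidy.sims_segmentation <- function(x, ...) x$layer_stats

#' @method glance sims_segmentation
#' @export
glance.sims_segmentation <- function(x, ...) {
  tibble::tibble(n_instances = nrow(x$instances),
                 n_live = sum(x$instances$class == "live"),
                 pct_live = 100 * mean(x$instances$class == "live"),
                 mean_cell_z_extent = x$mean_cell_z_extent)
}
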