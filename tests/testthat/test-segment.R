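# Clustering, semantic mapping, instance labelling, layer statistics.

test_that("well-separated clouds cluster exactly and degenerate input errors", {
  set.seed(13)
  # two composition clouds, each at arbitrary overall intensity
  a <- outer(runif(50, 1, 100), c(10, 1)) + matrix(abs(rnorm(100, sd = 0.2)), 50)
  b <- outer(runif(50, 1, 100), c(1, 10)) + matrix(abs(rnorm(100, sd = 0.2)), 50)
  cl <- cluster_voxels(rbind(a, b), n_clusters = 2, seed = 1)
  expect_equal(length(unique(cl[1:50])), 1)
  expect_equal(length(unique(cl[51:100])), 1)
  expect_false(cl[1] == cl[51])
  # identical rows cannot support more clusters than distinct points
  same <- matrix(1, 40, 3)
  expect_error(cluster_voxels(same, n_clusters = 3, seed = 1), "distinct")
  expect_error(cluster_voxels(same, n_clusters = 1), "n_clusters")
  # reproducibility under a fixed seed
  Z <- abs(matrix(rnorm(600), 200, 3))
  expect_identical(cluster_voxels(Z, 4, seed = 9), cluster_voxels(Z, 4, seed = 9))
})

test_that("segmentation is invariant to uniform rescaling of the scores", {
  sim <- small_sim(noise = "none", seed = 5)
  m <- fit_mcr(unfold_cube(sim$cube)$X, k = 4, weighting = "poisson")
  cl1 <- cluster_voxels(m$C, 4, seed = 2)
  cl2 <- cluster_voxels(m$C * 1e3, 4, seed = 2)
  expect_equal(as.integer(cl1), as.integer(cl2))
})

test_that("noise-free segmentation recovers every voxel class exactly", {
  sim <- small_sim(noise = "none", seed = 5)
  m <- fit_mcr(unfold_cube(sim$cube)$X, k = 4, weighting = "poisson")
  seg <- segment_cube(m, dim(sim$cube$counts)[1:3],
                      peaks = tiny_peaklist(10), n_clusters = 4, seed = 2)
  expect_equal(mean(seg$class_map == sim$class_map), 1)
})

test_that("noisy default segmentation reaches 90% voxel accuracy and 0.9 agreement", {
  skip_if_not_installed("mclust")
  sim <- small_sim(concentration = 1000, seed = 3)
  m <- fit_mcr(unfold_cube(sim$cube)$X, k = 6, weighting = "poisson")
  seg <- segment_cube(m, dim(sim$cube$counts)[1:3],
                      peaks = tiny_peaklist(10), seed = 2)
  # agreement between the semantic partition and the ground-truth
  # compartments (clusters are a refinement: several map to one class)
  ari <- mclust::adjustedRandIndex(as.vector(seg$class_map),
                                   as.vector(sim$class_map))
  expect_gt(ari, 0.9)
  expect_gte(mean(seg$class_map == sim$class_map), 0.9)
  # class partition covers every voxel
  expect_equal(sum(table(seg$class_map)), length(sim$class_map))
  # ablation: no K+ signal means no live cells
  cube0 <- sim$cube
  cube0$counts[, , , peak_index(cube0$peaks, c("K+", "Na+", "Ca+"))] <- 0
  m0 <- fit_mcr(unfold_cube(cube0)$X, k = 6, weighting = "poisson")
  expect_message(seg0 <- segment_cube(m0, dim(cube0$counts)[1:3],
                                      peaks = tiny_peaklist(10), seed = 2),
                 "unassigned")
  expect_equal(sum(seg0$class_map == "live"), 0)
  expect_gt(sum(seg0$class_map == "inactive"), 0)
})

test_that("semantic_map recovers classes from compartment-built clusters", {
  pk <- tiny_peaklist(0)
  tm <- unclass(build_templates(pk))
  sm <- apply(tm, 1, max)
  # scores = exact compartment indicators, factors = templates
  C <- kronecker(diag(4), matrix(1, 25, 1)) * rep(sm, each = 25)
  model <- structure(list(C = C, S = tm / sm, k = 4, peaks = pk$label),
                     class = "mcr_model")
  roles <- assign_factors(model, pk)
  clusters <- rep(1:4, each = 25)
  cls <- semantic_map(clusters, model, roles)
  expect_equal(unique(cls[1:25]), "live")
  expect_equal(unique(cls[26:50]), "inactive")
  expect_equal(unique(cls[51:75]), "aqueous")
  expect_equal(unique(cls[76:100]), "substrate")
  # a segmentation with no aqueous cluster is implausible and errors
  cells_only <- structure(list(C = C[1:50, ], S = tm / sm, k = 4,
                               peaks = pk$label), class = "mcr_model")
  expect_error(semantic_map(rep(1:2, each = 25), cells_only, roles),
               "aqueous")
})

test_that("cell instances follow the connectivity contract", {
  cm <- array("aqueous", c(10, 8, 8))
  cm[2:9, 2:3, 2:3] <- "live" # a 2x2x8 block
  lab <- label_cells(cm)
  expect_equal(nrow(lab$instances), 1)
  expect_equal(lab$instances$z_extent, 8)
  expect_equal(lab$instances$class, "live")

  # two blocks touching only at a corner: one instance under
  # 26-connectivity, two under 6-connectivity
  cm2 <- array("aqueous", c(4, 6, 6))
  cm2[1:2, 1:2, 1:2] <- "inactive"
  cm2[3:4, 3:4, 3:4] <- "inactive"
  expect_equal(nrow(label_cells(cm2, connectivity = 26)$instances), 1)
  expect_equal(nrow(label_cells(cm2, connectivity = 6)$instances), 2)
  # small specks are discarded
  cm3 <- array("aqueous", c(4, 4, 4))
  cm3[1, 1, 1] <- "live"
  expect_equal(nrow(label_cells(cm3, min_voxels = 4)$instances), 0)
})

test_that("instance counts on gap-separated truth match the generator", {
  sim <- small_sim(noise = "none", seed = 5)
  lab <- label_cells(sim$class_map)
  n_true <- nrow(sim$truth$cells)
  expect_lte(abs(nrow(lab$instances) - n_true), ceiling(0.1 * n_true))
  expect_equal(mean(lab$instances$z_extent), 8, tolerance = 0.01)
})

test_that("layer statistics count 2-D components and flag empty layers", {
  cm <- array("aqueous", c(10, 8, 8))
  cm[2:9, 2:3, 2:3] <- "live"
  ls <- layer_stats(cm, label_cells(cm)$instances)
  expect_equal(ls$n_cells[1], 0)
  expect_true(is.na(ls$pct_live[1]))
  expect_equal(ls$n_cells[2:9], rep(1, 8))
  expect_equal(ls$pct_live[2], 100)
  expect_equal(attr(ls, "mean_cell_z_extent"), 8)
  # empty map: all zeros, undefined percentages
  empty <- array("aqueous", c(3, 4, 4))
  ls0 <- layer_stats(empty, label_cells(empty)$instances)
  expect_true(all(ls0$n_cells == 0))
  expect_true(all(is.na(ls0$pct_live)))
})

test_that("per-layer counts fall off above the dense basal block", {
  sim <- small_sim(noise = "none", seed = 5, grid = c(24, 64, 64),
                   n_cells = 40)
  ls <- layer_stats(sim$class_map)
  n <- ls$n_cells
  # compare the mean count in the three deepest cell-bearing layers with
  # the mean in the three outermost cell-bearing layers
  occupied <- which(n > 0)
  expect_gt(mean(n[tail(occupied, 3)]), mean(n[head(occupied, 3)]))
})
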