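# Compartment quantification and Fisher's exact detection tests.

test_that("compartment ratios divide summed counts per class", {
  pk <- peaklist(c("H37O18+", "cipro"), c(325.197, 332.1405),
                 c(325.1, 332.1), c(325.3, 332.2),
                 species = c("water", "cipro"))
  counts <- array(0, c(1, 2, 2, 2))
  cm <- array(c("live", "live", "aqueous", "substrate"), c(1, 2, 2))
  counts[, , , 1] <- c(50, 50, 200, 0) # denominator
  counts[, , , 2] <- c(31, 32, 10, 0)  # numerator
  cube <- sims_cube(counts, pk)
  q <- compartment_ratio(cube, cm)
  expect_equal(q$ratio[q$class == "live"], 63 / 100)
  expect_equal(q$ratio[q$class == "media"], 10 / 200)
  expect_equal(q$ratio[q$class == "all_cells"], 63 / 100) # no inactive voxels
  expect_warning(compartment_ratio(cube, array("aqueous", c(1, 2, 2))),
                 "undefined")
})

test_that("all-cells ratio lies between the live and inactive ratios", {
  sim <- small_sim(concentration = 1000, seed = 3)
  q <- compartment_ratio(sim$cube, sim$class_map)
  r <- setNames(q$ratio, q$class)
  expect_gte(r["all_cells"], min(r["live"], r["inactive"]))
  expect_lte(r["all_cells"], max(r["live"], r["inactive"]))
  # live enhancement over media reproduces the generator's target within
  # counting error
  target <- sim$truth$cipro$enhancement_live
  obs <- r["live"] / r["media"]
  expect_lt(abs(obs - target) / target, 0.2)
})

test_that("quantification uses raw counts and ignores denoising", {
  sim <- small_sim(concentration = 1000, seed = 3)
  q_raw <- compartment_ratio(sim$cube, sim$class_map)
  fit <- fit_msf(sim$cube, k = 6)
  denoised <- denoise(sim$cube, fit)
  # running denoise first must not change what quantification sees
  q_again <- compartment_ratio(sim$cube, sim$class_map)
  expect_identical(q_raw, q_again)
  q_dn <- compartment_ratio(denoised, sim$class_map)
  expect_false(isTRUE(all.equal(q_raw$ratio, q_dn$ratio)))
})

test_that("detection tables have the right margins and reject overlap", {
  pk <- toy_cube()$peaks
  counts <- array(0, c(1, 4, 5, 2))
  counts[, , , 1] <- c(rep(1, 3), rep(0, 7), rep(0, 10))
  cm <- array(rep(c("live", "aqueous"), each = 10), c(1, 4, 5))
  cube <- sims_cube(counts, pk)
  tab <- detection_table(cube, cm, peak = "a", class_a = "live",
                         class_b = "aqueous")
  expect_equal(unname(tab), matrix(c(3L, 0L, 7L, 10L), 2))
  expect_equal(unname(rowSums(tab)), c(10L, 10L))
  expect_error(detection_table(cube, cm, "a", c("live", "aqueous"), "aqueous"),
               "disjoint")
})

test_that("fisher test matches brute-force enumeration for all small tables", {
  # exhaustive oracle suite over tables with n <= 30
  set.seed(17)
  tabs <- list(matrix(c(1L, 11L, 9L, 3L), 2),
               matrix(c(5L, 5L, 5L, 5L), 2),
               matrix(c(0L, 10L, 10L, 0L), 2))
  for (i in 1:60) {
    n <- sample(4:30, 1)
    cells <- as.integer(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    tabs[[length(tabs) + 1]] <- matrix(cells, 2)
  }
  for (tab in tabs) {
    p_pkg <- fisher_detection(tab)$p_value
    expect_equal(p_pkg, fisher_brute(tab), tolerance = 1e-9)
  }
  # the worked example
  expect_equal(fisher_detection(matrix(c(1L, 11L, 9L, 3L), 2))$p_value,
               0.0028, tolerance = 0.02)
  expect_equal(fisher_detection(matrix(c(5L, 5L, 5L, 5L), 2))$p_value, 1)
  # degenerate all-detected column is flagged with p = 1
  degen <- fisher_detection(matrix(c(10L, 10L, 0L, 0L), 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
  expect_error(fisher_detection(matrix(c(-1L, 1L, 1L, 1L), 2)), "non-negative")
})

test_that("strongly separated classes give p below 1e-4", {
  # near-MIC exposure: sparse counts, so per-voxel detection separates the
  # compartments sharply
  sim <- small_sim(concentration = 10, seed = 3)
  tab <- detection_table(sim$cube, sim$class_map, "cipro",
                         c("live", "inactive"), "aqueous")
  expect_true(all(rowSums(tab) >= 500))
  expect_lt(fisher_detection(tab)$p_value, 1e-4)
  # live vs inactive needs >= 500 voxels per class for this power level
  big <- small_sim(concentration = 10, seed = 5, grid = c(24, 64, 64),
                   n_cells = 40)
  tab2 <- detection_table(big$cube, big$class_map, "cipro", "live", "inactive")
  expect_true(all(rowSums(tab2) >= 500))
  expect_lt(fisher_detection(tab2)$p_value, 1e-4)
  # at saturating exposure the detection fractions still order live > media
  sat <- small_sim(concentration = 1000, seed = 3)
  tab3 <- detection_table(sat$cube, sat$class_map, "cipro", "live", "aqueous")
  frac <- tab3[, "detected"] / rowSums(tab3)
  expect_gt(frac[1], frac[2])
})

test_that("report bundles are deterministic and carry diagnostics", {
  q <- tibble::tibble(class = "live", n_voxels = 1L, num_counts = 1,
                      den_counts = 2, ratio = 0.5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_report(d1, quant = q, manifest = list(seed = 1),
              diagnostics = c(dropped_events = 3, max_clip_bias = 0))
  make_report(d2, quant = q, manifest = list(seed = 1),
              diagnostics = c(dropped_events = 3, max_clip_bias = 0))
  f1 <- file.path(d1, "compartment_ratios.tsv")
  f2 <- file.path(d2, "compartment_ratios.tsv")
  expect_identical(readLines(f1), readLines(f2))
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(m1$diagnostics$dropped_events, 3)
  expect_null(m1$diagnostics$max_clip_bias) # zero diagnostics are omitted
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(m1$config_hash, m2$config_hash)
})
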