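# Synthetic biofilm generator: templates, cipro model, cell placement,
# forward model.

test_that("templates implement the compartment spectral rules", {
  pk <- tiny_peaklist()
  tm <- build_templates(pk, water_amplitude = 10, water_decay = 0)
  wat <- pk$species == "water"
  # zero decay: every water cluster mean equals the amplitude
  expect_equal(unname(unclass(tm)["aqueous", wat]), rep(10, sum(wat)))

  tm <- build_templates(pk)
  org <- pk$species == "organic"
  salts <- pk$species %in% c("salt_K", "salt_Na", "salt_Ca")
  # live and inactive differ only at the viability salt channels
  expect_equal(unclass(tm)["live", !salts], unclass(tm)["inactive", !salts])
  expect_true(all(unclass(tm)["live", salts] > 0))
  expect_true(all(unclass(tm)["inactive", salts] == 0))
  # aqueous template: no organics (m/z 70.07 included), no K+
  expect_equal(unname(unclass(tm)["aqueous", org]), rep(0, sum(org)))
  expect_equal(unname(unclass(tm)["aqueous", pk$label == "K+"]), 0)
  # only the substrate carries Al+, and nothing else
  al <- pk$species == "substrate_Al"
  expect_true(unclass(tm)["substrate", al] > 0)
  expect_equal(sum(unclass(tm)["substrate", !al]), 0)
  expect_equal(unname(unclass(tm)[c("live", "inactive", "aqueous"), al]),
               rep(0, 3))
  # water series decays exponentially at the configured rate
  n <- as.numeric(sub("^H\\d+O(\\d+)\\+$", "\\1", pk$label[wat]))
  expect_equal(unname(unclass(tm)["aqueous", wat]),
               2000 * exp(-0.25 * n))
  expect_error(build_templates(pk, water_amplitude = -1), "non-negative")
})

test_that("cipro model reproduces the published compartment enhancements", {
  cm <- cipro_model(1000)
  expect_equal(cm$baseline_ratio_aqueous, 0.22)
  expect_equal(cm$enhancement_live, 0.63 / 0.22)
  expect_equal(cm$enhancement_inactive, 0.33 / 0.22)
  expect_gt(cm$background_ratio_at_zero, 0)
  expect_true(cm$enhancement_live >= cm$enhancement_inactive)
  expect_true(cm$enhancement_inactive >= 1)
  zero <- cipro_model(0)
  expect_equal(zero$baseline_ratio_aqueous, 7.4e-4)
})

test_that("place_cells follows the seed, the live fraction and the geometry", {
  t1 <- place_cells(grid = c(24, 64, 64), n_cells = 40, seed = 7)
  t2 <- place_cells(grid = c(24, 64, 64), n_cells = 40, seed = 7)
  expect_identical(t1$cells, t2$cells)

  none <- place_cells(grid = c(24, 64, 64), n_cells = 30, live_fraction = 0,
                      seed = 1)
  expect_equal(sum(none$cells$type == "live"), 0)

  # observed live share within the binomial 99% interval of 0.36
  big <- place_cells(grid = c(24, 256, 256), n_cells = 200,
                     live_fraction = 0.36, seed = 5)
  share <- mean(big$cells$type == "live")
  half <- qnorm(0.995) * sqrt(0.36 * 0.64 / 200)
  expect_gt(share, 0.36 - half)
  expect_lt(share, 0.36 + half)

  # infeasible packing densities error out
  expect_error(place_cells(grid = c(24, 16, 16), n_cells = 500, seed = 1,
                           max_attempts = 20),
               "packing infeasible")
})

test_that("the truth class map respects the layered geometry", {
  truth <- small_sim()$truth
  cm <- truth_class_map(truth)
  nz <- truth$grid[1]
  # substrate occupies exactly the deepest layers
  expect_true(all(cm[(nz - 2):nz, , ] == "substrate"))
  # outer surface layers are cell-free aqueous
  expect_true(all(cm[1:4, , ] %in% "aqueous"))
  # every placed cell spans 8 layers in the map
  lab <- cryosims:::connected_components(
    array(cm %in% c("live", "inactive"), dim(cm)), 26)
  ext <- tapply(arrayInd(which(lab > 0), dim(lab))[, 1], lab[lab > 0],
                function(z) diff(range(z)) + 1)
  expect_equal(as.vector(ext), rep(8, nrow(truth$cells)))
})

test_that("noise-free rendering equals the analytic expectation", {
  sim <- small_sim(noise = "none", seed = 5)
  cube <- sim$cube
  pk <- cube$peaks
  tm <- sim$truth$templates
  cip <- sim$truth$cipro
  # an aqueous voxel's spectrum equals the aqueous template plus the cipro
  # contribution at the (M+H)+ channel
  aq <- which(sim$class_map == "aqueous", arr.ind = TRUE)[1, ]
  spec <- cube$counts[aq[1], aq[2], aq[3], ]
  expected <- unclass(tm)["aqueous", ]
  den <- expected[pk$label == "H37O18+"]
  expected[pk$label == "cipro"] <- cip$baseline_ratio_aqueous * den
  expect_equal(unname(spec), unname(expected), tolerance = 1e-12)
  # determinism of the noise-free path
  sim2 <- small_sim(noise = "none", seed = 5)
  expect_identical(sim$cube$counts, sim2$cube$counts)
  # doubling all template amplitudes doubles the expected total ion count
  tm2 <- build_templates(tiny_peaklist(10), water_amplitude = 4000,
                         organic_amplitude = 100,
                         salt_amplitudes = c(K = 200, Na = 60, Ca = 20),
                         substrate_amplitude = 1000, background_level = 0.1)
  r2 <- render_cube(sim$truth, templates = tm2, cipro = cip, noise = "none")
  expect_equal(sum(r2$cube$counts), 2 * sum(cube$counts), tolerance = 1e-9)
  # geometry of map and cube always agree
  expect_equal(dim(sim$class_map), dim(cube$counts)[1:3])
})

test_that("rendered compartment ratios match the forward model within noise", {
  sim <- small_sim(concentration = 1000, seed = 3)
  cube <- sim$cube
  num <- peak_channel(cube, "cipro")
  den <- peak_channel(cube, "H37O18+")
  live <- sim$class_map == "live"
  ratio_live <- sum(num[live]) / sum(den[live])
  target <- 0.63 # live-cell table value at 1000 ug/ml
  se <- target * sqrt(1 / sum(num[live]) + 1 / sum(den[live]))
  expect_lt(abs(ratio_live - target), 4 * se)
})

test_that("zero-concentration renders a flat metastable background", {
  sim <- small_sim(concentration = 0, seed = 9)
  cip <- peak_channel(sim$cube, "cipro")
  floor_counts <- sim$truth$cipro$background_ratio_at_zero *
    unclass(sim$truth$templates)["aqueous", "H37O18+"]
  # mean equals the metastable floor, with no trend in z
  expect_equal(mean(cip), floor_counts, tolerance = 0.15)
  per_layer <- apply(cip, 1, mean)
  fit <- lm(per_layer ~ seq_along(per_layer))
  expect_gt(summary(fit)$coefficients[2, 4], 0.01) # slope not significant
})

test_that("detector saturation attenuates the brightest water channels", {
  sim_lin <- small_sim(noise = "none", seed = 5)
  truth <- sim_lin$truth
  sat <- render_cube(truth, noise = "none", saturation_tau = 1e-4)
  h3o <- peak_channel(sat$cube, "H3O1+") # brightest water channel
  h3o_lin <- peak_channel(sim_lin$cube, "H3O1+")
  expect_true(all(h3o <= h3o_lin + 1e-9))
  expect_lt(max(h3o), max(h3o_lin)) # attenuation strictly at high intensity
  # non-water channels untouched
  expect_equal(peak_channel(sat$cube, "K+"), peak_channel(sim_lin$cube, "K+"))
})
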