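# Depth profiles, region labelling, region ratios and calibration.

test_that("extract_profile sums layers and rejects empty subsets", {
  cube <- toy_cube()
  pr <- extract_profile(cube)
  expect_equal(sort(unique(pr$label)), c("a", "b"))
  for (z in 1:2) for (lb in c("a", "b")) {
    expect_equal(pr$counts[pr$layer == z & pr$label == lb],
                 sum(cube$counts[z, , , peak_index(cube$peaks, lb)]))
  }
  # single-layer cube: profile equals the grand totals
  one <- toy_cube(array(2, c(1, 3, 4, 2)), 1, 3, 4)
  pr1 <- extract_profile(one)
  expect_equal(pr1$counts, c(24, 24))
  # all-zero cube gives an all-zero table
  zc <- toy_cube(array(0, c(2, 3, 4, 2)))
  expect_true(all(extract_profile(zc)$counts == 0))
  expect_error(extract_profile(cube, character()), "empty")
})

test_that("region labelling finds the onset from a step profile", {
  mk <- function(marker, al) {
    dplyr::bind_rows(
      tibble::tibble(layer = seq_along(marker), label = "C4H8N+", counts = marker),
      tibble::tibble(layer = seq_along(marker), label = "C2H6N+", counts = marker),
      tibble::tibble(layer = seq_along(marker), label = "C5H10N+", counts = marker),
      tibble::tibble(layer = seq_along(al), label = "Al+", counts = al))
  }
  # biofilm onset at the 4th layer (first exceeding 10% of max)
  pr <- label_regions(mk(c(0, 0, 0, 100, 100, 100, 100, 0),
                         c(0, 0, 0, 0, 0, 0, 200, 200)))
  reg <- dplyr::distinct(pr, .data$layer, .data$region)$region
  expect_equal(reg[1:2], c("aqueous", "aqueous"))
  expect_equal(reg[3:4], c("interface", "interface"))
  expect_equal(reg[5], "biofilm")
  expect_equal(reg[8], "substrate")
  expect_equal(reg[6:7], c("interface", "interface"))

  # scale invariance and idempotence
  pr_scaled <- label_regions(dplyr::mutate(mk(
    c(0, 0, 0, 100, 100, 100, 100, 0), c(0, 0, 0, 0, 0, 0, 200, 200)),
    counts = .data$counts * 37.5))
  expect_equal(dplyr::distinct(pr_scaled, .data$layer, .data$region)$region, reg)
  relabelled <- label_regions(pr)
  expect_equal(relabelled$region, pr$region)

  # markers never above threshold: all aqueous, with a warning
  expect_warning(pr0 <- label_regions(mk(rep(0, 5), rep(0, 5))), "aqueous")
  expect_true(all(pr0$region == "aqueous"))
})

test_that("labelled biofilm span overlaps the true cell-occupied span", {
  sim <- small_sim(noise = "none", seed = 5)
  pr <- label_regions(extract_profile(sim$cube))
  cell_layers <- which(apply(sim$class_map, 1, function(l) {
    any(l %in% c("live", "inactive"))
  }))
  lab <- dplyr::distinct(pr, .data$layer, .data$region)
  bio <- lab$layer[lab$region == "biofilm"]
  overlap <- mean(bio %in% cell_layers)
  expect_gte(overlap, 0.9)
  # noise off: aqueous layers carry no organic signal at all
  aq <- lab$layer[lab$region == "aqueous"]
  organic <- pr$counts[pr$label == "C4H8N+" & pr$layer %in% aq]
  expect_true(all(organic == 0))
})

test_that("region_ratio divides summed counts and aggregates replicates", {
  pr <- tibble::tibble(
    layer = rep(1:2, each = 2),
    label = rep(c("cipro", "H25O12+"), 2),
    counts = c(3, 500, 3, 500),
    region = "aqueous")
  rr <- region_ratio(pr)
  expect_equal(rr$ratio, 6 / 1000)
  # replicate mean and (n-1) sd shaped like the published table cells
  reps <- lapply(c(0.0057, 0.0060, 0.0063), function(r) {
    dplyr::mutate(pr, counts = ifelse(.data$label == "cipro",
                                      r * 500, .data$counts))
  })
  rs <- region_ratio(reps)
  expect_equal(rs$n, 3)
  expect_equal(rs$ratio, 0.0060, tolerance = 1e-9)
  expect_equal(rs$sd, 0.0003, tolerance = 1e-9)
  # uniform positive rescaling leaves the ratio unchanged
  rr2 <- region_ratio(dplyr::mutate(pr, counts = .data$counts * 12.3))
  expect_equal(rr2$ratio, rr$ratio)
  expect_error(region_ratio(pr, "biofilm"), "no non-interface layers")
  pr0 <- dplyr::mutate(pr, counts = ifelse(.data$label == "H25O12+", 0,
                                           .data$counts))
  expect_error(region_ratio(pr0), "zero denominator")
})

test_that("calibration fit matches the closed-form least squares", {
  # exactly collinear points
  fit <- calibration_fit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$residuals, rep(0, 3), tolerance = 1e-12)
  expect_error(calibration_fit(c(1, 2), c(1, 2)), "at least 3")

  ref <- dplyr::filter(depth_ratio_reference(), region == "aqueous")
  fit <- calibration_fit(ref$concentration, ref$ratio)
  x <- ref$concentration; y <- ref$ratio
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(fit$r_squared, sxy^2 / (sxx * syy), tolerance = 1e-9)
  expect_equal(fit$slope, sxy / sxx, tolerance = 1e-12)
  g <- glance(fit)
  expect_equal(g$r.squared, fit$r_squared)
  expect_equal(nrow(tidy(fit)), 2)
})
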