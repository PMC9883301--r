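# Noise-whitened low-rank denoising and its validation statistics.

test_that("pure-noise eigenvalues sit at the unit noise level", {
  set.seed(21)
  mu <- runif(30, 0.5, 20)
  X <- sapply(mu, function(m) rpois(3000, m))
  fit <- fit_msf(X, k = 5)
  # whitened i.i.d. Poisson noise has unit variance; the leading
  # eigenvalues exceed 1 only by Marchenko-Pastur-scale fluctuation
  mp_edge <- (1 + sqrt(30 / 3000))^2
  expect_lt(fit$eigenvalues[1], mp_edge * 1.1)
  expect_gt(fit$eigenvalues[1], 0.9)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
})

test_that("noiseless low-rank signal is reconstructed essentially exactly", {
  set.seed(22)
  C <- cbind(runif(500, 0, 10), runif(500, 0, 5))
  S <- rbind(runif(20, 0, 4), runif(20, 0, 4))
  X <- C %*% S + matrix(runif(500 * 20, 0, 1e-6), 500, 20)
  fit <- fit_msf(X, k = 2)
  Xh <- denoise(X, fit)
  expect_lt(sqrt(sum((Xh - X)^2)) / sqrt(sum(X^2)), 1e-6)
})

test_that("k = n_peaks reproduces the input exactly", {
  set.seed(23)
  X <- matrix(rpois(400 * 8, 6), 400, 8)
  fit <- fit_msf(X, k = 8)
  Xh <- denoise(X, fit)
  expect_lt(max(abs(Xh - X)), 1e-9)
  expect_equal(max(abs(attr(Xh, "clip_bias"))), 0, tolerance = 1e-12)
})

test_that("fit_msf validates inputs and flags zero columns", {
  X <- matrix(rpois(100 * 4, 3), 100, 4)
  expect_error(fit_msf(X - 10, k = 2), "non-negative")
  expect_error(fit_msf(X, k = 9), "rank bound")
  X0 <- cbind(X, 0)
  expect_warning(fit_msf(X0, k = 2), "all-zero")
  # loadings orthonormal in the whitened metric
  fit <- fit_msf(X, k = 3)
  expect_equal(crossprod(fit$V), diag(3), tolerance = 1e-8)
})

test_that("the shift-difference noise estimate tracks Poisson variance", {
  # on a spatially homogeneous cube the one-layer z-difference is pure
  # noise, so half its mean square equals the Poisson variance
  set.seed(27)
  mu <- runif(12, 2, 40)
  X <- sapply(mu, function(m) rpois(10 * 20 * 20, m))
  fit_p <- fit_msf(X, k = 3, noise_model = "poisson_diag")
  fit_s <- fit_msf(X, k = 3, noise_model = "shift_difference",
                   dims = c(10, 20, 20))
  expect_true(all(fit_s$d / fit_p$d > 0.85))
  expect_true(all(fit_s$d / fit_p$d < 1.18))
  # sharp z-structure inflates the shift estimate above the Poisson level
  # (it charges composition steps to noise): structured synthetic cube
  sim <- small_sim(seed = 5)
  sp <- fit_msf(sim$cube, k = 6, noise_model = "poisson_diag")
  ss <- fit_msf(sim$cube, k = 6, noise_model = "shift_difference")
  al <- which(sim$cube$peaks$label == "Al+")
  expect_gt(ss$d[al] / sp$d[al], 2)
})

test_that("denoising reduces error against the noiseless truth at the analyte channel", {
  clean <- small_sim(concentration = 1000, seed = 3, noise = "none")
  noisy <- small_sim(concentration = 1000, seed = 3)
  Xc <- unfold_cube(clean$cube)$X
  Xn <- unfold_cube(noisy$cube)$X
  fit <- fit_msf(Xn, k = 6)
  Xh <- denoise(Xn, fit)
  j <- which(colnames(Xn) == "cipro")
  mse_raw <- mean((Xn[, j] - Xc[, j])^2)
  mse_hat <- mean((Xh[, j] - Xc[, j])^2)
  expect_lt(mse_hat, mse_raw)
  # denoised cube keeps geometry, peak list and non-negativity
  cube_hat <- denoise(noisy$cube, fit)
  expect_equal(dim(cube_hat$counts), dim(noisy$cube$counts))
  expect_identical(cube_hat$peaks$label, noisy$cube$peaks$label)
  expect_true(all(cube_hat$counts >= 0))
  # denoised antibiotic map is brighter in cells than in the medium
  cz <- peak_channel(cube_hat, "cipro")
  cells <- clean$class_map %in% c("live", "inactive")
  aq <- clean$class_map == "aqueous"
  expect_gt(mean(cz[cells]), mean(cz[aq]))
})

test_that("validation statistics satisfy their exact identities", {
  sim <- small_sim(seed = 5)
  X <- unfold_cube(sim$cube)$X
  fit <- fit_msf(X, k = 6)
  li <- rep(seq_len(16), each = 40 * 40)
  # X-hat = X: perfect correlation, zero deviation
  v <- validate_denoise(X, X, fit, layer_index = li,
                        class_map = sim$class_map)
  expect_true(all(abs(v$peak_stats$R_j2 - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(v$class_stats$deviation == 0, na.rm = TRUE))
  # well-specified fit: no lack of fit on the antibiotic channel
  Xh <- denoise(X, fit)
  v2 <- validate_denoise(X, Xh, fit, layer_index = li,
                         class_map = sim$class_map, peaks = "cipro")
  expect_lt(v2$peak_stats$F_j, 0.99)
  expect_gt(v2$peak_stats$R_j2, 0.99)
  # classes with enough raw counts to estimate a mean at the 10% level
  well_counted <- v2$class_stats$raw_counts >= 100
  expect_true(any(well_counted))
  expect_true(all(v2$class_stats$deviation[well_counted] <= 0.10, na.rm = TRUE))
})

test_that("a deliberately under-fitted model shows lack of fit", {
  sim <- small_sim(seed = 5)
  X <- unfold_cube(sim$cube)$X
  fit1 <- fit_msf(X, k = 1)
  Xh <- denoise(X, fit1)
  v <- validate_denoise(X, Xh, fit1,
                        layer_index = rep(seq_len(16), each = 1600))
  organic <- biofilm_organic_ions()$assignment
  bad <- v$peak_stats$F_j[v$peak_stats$label %in% organic]
  expect_true(any(bad >= 0.99))
})

test_that("on pure noise about 1% of peaks show F_j >= 0.99", {
  set.seed(31)
  n_peaks <- 600
  X <- sapply(runif(n_peaks, 1, 10), function(m) rpois(2000, m))
  fit <- fit_msf(X, k = 3)
  Xh <- denoise(X, fit)
  v <- validate_denoise(X, Xh, fit, layer_index = rep(1:10, each = 200))
  frac <- mean(v$peak_stats$F_j >= 0.99)
  # binomial band around the nominal 1% level
  expect_lt(frac, 0.01 + 3 * sqrt(0.01 * 0.99 / n_peaks))
})
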