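# Shared fixtures, all built in code. Small grids keep the default test run
# fast; the acceptance tests build the full-size study cube once and share
# it across criteria via lazy memoisation.

tiny_peaklist <- function(n_background = 5) {
  # n_water = 18 keeps both normalization denominators (H25O12+, H37O18+)
  default_peaklist(n_water = 18, n_background = n_background)
}

# a minimal hand-built cube: known counts, 2 peaks
toy_cube <- function(counts = NULL, nz = 2, ny = 3, nx = 4) {
  pk <- peaklist(c("a", "b"), c(100, 200), c(99.9, 199.9), c(100.1, 200.1))
  if (is.null(counts)) {
    counts <- array(seq_len(nz * ny * nx * 2), c(nz, ny, nx, 2))
  }
  sims_cube(counts, pk, pixel_size_um = 0.5, provenance = "toy")
}

# small but complete synthetic measurement, memoised per parameter set
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function(concentration = 1000, seed = 3, noise = "poisson",
                      grid = c(16, 40, 40), n_cells = 20, n_background = 10,
                      ...) {
  key <- paste(concentration, seed, noise, paste(grid, collapse = "x"),
               n_cells, n_background, ...)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_biofilm(
      concentration = concentration, grid = grid, n_cells = n_cells,
      peaks = tiny_peaklist(n_background), noise = noise, seed = seed, ...)
  }
  .sim_cache[[key]]
}

# brute-force two-sided Fisher p-value by full enumeration over tables with
# the observed margins (point-probability method)
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    stats::dhyper(a, r1, r2, c1)
  }, numeric(1))
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
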