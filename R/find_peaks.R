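# Automated peak search on a summed spectrum.
#
# A summed spectrum is a tibble with columns `mz` (uniform, strictly
# increasing grid) and `counts` (non-negative totals per channel). The
# search returns local maxima above a noise floor, each with an integration
# window extending to the flanking minima and clipped at +/- half the
# minimum separation. The procedure is fully deterministic.

#' Automated peak search on a summed spectrum
#'
#' Finds local maxima whose height exceeds both a noise floor (a multiple of
#' the median of the nonzero channels) and a prominence threshold (a
#' fraction of the spectrum maximum). Peaks closer than `min_separation_mz`
#' are merged, keeping the taller one. Each peak's integration window runs
#' from the flanking local minima, clipped at half the minimum separation on
#' either side, and windows never overlap.
#'
#' @param spectrum Tibble with columns `mz` (uniform strictly increasing
#'   grid) and `counts` (non-negative).
#' @param min_prominence Minimum peak height as a fraction of the spectrum
#'   maximum (default 1e-5).
#' @param min_separation_mz Minimum centre-to-centre separation (u); peaks
#'   closer than this are merged (default 0.05).
#' @param noise_mult Noise floor multiplier: peaks must exceed
#'   `noise_mult` times the median of the nonzero channels (default 3).
#' @return A peak-list tibble ([peaklist()]); empty (0 rows) for an all-zero
#'   spectrum.
#' @export
find_peaks <- function(spectrum, min_prominence = 1e-5,
                       min_separation_mz = 0.05, noise_mult = 3) {
  if (!all(c("mz", "counts") %in% names(spectrum)) || nrow(spectrum) == 0) {
    abort("spectrum must be a non-empty tibble with columns mz, counts")
  }
  mz <- spectrum$mz
  y <- spectrum$counts
  if (is.unsorted(mz, strictly = TRUE)) abort("mz axis must be strictly increasing")
  stop_if_negative(y, "spectrum counts")
  if (all(y == 0)) {
    return(peaklist(character(), numeric(), numeric(), numeric())[0, ])
  }
  nz <- y[y > 0]
  floor_level <- max(noise_mult * stats::median(nz), min_prominence * max(y))
  n <- length(y)
  # strict local maxima (plateaus: leftmost channel of the plateau)
  left <- c(Inf, y[-n])
  right <- c(y[-1], Inf)
  is_max <- y > left & y >= right & y > floor_level
  cand <- which(is_max)
  if (length(cand) == 0) {
    return(peaklist(character(), numeric(), numeric(), numeric())[0, ])
  }
  # merge peaks closer than min_separation_mz, keeping the taller
  cand <- cand[order(mz[cand])]
  keep <- logical(length(cand))
  i <- 1
  while (i <= length(cand)) {
    j <- i
    while (j < length(cand) && mz[cand[j + 1]] - mz[cand[j]] < min_separation_mz) {
      j <- j + 1
    }
    grp <- cand[i:j]
    keep[i:j] <- FALSE
    keep[i + which.max(y[grp]) - 1] <- TRUE
    i <- j + 1
  }
  cand <- cand[keep]
  half_sep <- min_separation_mz / 2
  lo <- hi <- numeric(length(cand))
  for (k in seq_along(cand)) {
    p <- cand[k]
    i <- p
    while (i > 1 && y[i - 1] < y[i]) i <- i - 1
    j <- p
    while (j < n && y[j + 1] < y[j]) j <- j + 1
    lo[k] <- max(mz[i], mz[p] - half_sep)
    hi[k] <- min(mz[j], mz[p] + half_sep)
    step <- mz[2] - mz[1]
    if (lo[k] >= mz[p]) lo[k] <- mz[p] - step / 2
    if (hi[k] <= mz[p]) hi[k] <- mz[p] + step / 2
  }
  # enforce non-overlap between consecutive windows
  if (length(cand) > 1) {
    for (k in seq_len(length(cand) - 1)) {
      if (hi[k] > lo[k + 1]) {
        mid <- (mz[cand[k]] + mz[cand[k + 1]]) / 2
        hi[k] <- min(hi[k], mid)
        lo[k + 1] <- max(lo[k + 1], mid)
      }
    }
  }
  peaklist(sprintf("mz%.4f", mz[cand]), mz[cand], lo, hi,
           assignment = "unassigned")
}
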