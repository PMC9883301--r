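# Noise-whitened low-rank denoising of peak-picked count images, with the
# per-peak validation statistics used to certify that denoising has not
# distorted the analyte signal.
#
# Model: each peak column is scaled by the inverse square root of its noise
# variance (Poisson: the column mean; alternatively half the mean squared
# one-layer z-difference), mean-centered, and the top-k singular directions
# of the whitened matrix are retained. Reconstruction projects onto those
# directions, un-centers, un-whitens and clips negatives to zero. In the
# whitened metric pure counting noise has unit variance in every direction,
# so the retained eigenvalues read directly as signal-to-noise ratios and
# the residual mean square per peak can be referred to an F distribution.

#' Fit a noise-whitened low-rank denoiser
#'
#' @param X Non-negative count matrix (voxels x peaks, see
#'   [unfold_cube()]) or a [sims_cube()].
#' @param k Number of retained factors (default 10).
#' @param noise_model `"poisson_diag"` (per-peak variance = column mean;
#'   default) or `"shift_difference"` (half the mean squared one-voxel
#'   difference along z; requires a cube or `dims`).
#' @param dims Integer (nz, ny, nx), required for `"shift_difference"` when
#'   `X` is a matrix.
#' @param center Mean-center columns before the SVD (default TRUE).
#' @param eps Variance floor for all-zero columns (default 1e-3 counts).
#' @return An `msf_denoiser`: list with `d` (per-peak noise variance),
#'   `mean_spectrum`, `V` (peaks x k loadings, orthonormal in the whitened
#'   metric), `eigenvalues` (k signal-to-noise ratios, non-increasing),
#'   `k`, `noise_model`, `center`, `n` (voxels).
#' @export
fit_msf <- function(X, k = 10, noise_model = c("poisson_diag", "shift_difference"),
                    dims = NULL, center = TRUE, eps = 1e-3) {
  noise_model <- match.arg(noise_model)
  if (inherits(X, "sims_cube")) {
    dims <- dim(X$counts)[1:3]
    X <- unfold_cube(X)$X
  }
  if (any(X < 0)) abort("X must contain non-negative counts")
  if (k < 1) abort("k must be >= 1")
  if (k > min(dim(X))) abort(sprintf("k = %d exceeds the rank bound min(dim) = %d",
                                     k, min(dim(X))))
  mu <- colMeans(X)
  d <- switch(noise_model,
    poisson_diag = pmax(mu, eps),
    shift_difference = {
      if (is.null(dims)) abort("shift_difference requires dims (or a cube input)")
      if (dims[1] < 2) abort("shift_difference requires at least 2 layers")
      n_per_layer <- dims[2] * dims[3]
      a <- X[seq_len((dims[1] - 1) * n_per_layer) + n_per_layer, , drop = FALSE] -
        X[seq_len((dims[1] - 1) * n_per_layer), , drop = FALSE]
      pmax(colMeans(a^2) / 2, eps)
    }
  )
  if (any(mu == 0)) {
    warn(sprintf("%d all-zero peak columns; their noise variance floored at eps",
                 sum(mu == 0)))
  }
  w <- 1 / sqrt(d)
  n <- nrow(X)
  Xw <- sweep(X, 2, w, "*")
  ctr <- if (center) colMeans(Xw) else rep(0, ncol(X))
  G <- crossprod(Xw) / n - tcrossprod(ctr)   # covariance about the mean
  rm(Xw)
  gc(verbose = FALSE)
  eg <- eigen(G, symmetric = TRUE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  structure(list(d = d, mean_spectrum = mu, V = V,
                 eigenvalues = eg$values[seq_len(k)],
                 all_eigenvalues = eg$values,
                 k = k, noise_model = noise_model, center = center,
                 n = nrow(X)),
            class = "msf_denoiser")
}

#' @export
print.msf_denoiser <- function(x, ...) {
  cat(sprintf("<msf_denoiser> k = %d of %d peaks (%s noise), leading SNR eigenvalues: %s\n",
              x$k, length(x$d), x$noise_model,
              paste(signif(head(x$eigenvalues, 5), 3), collapse = ", ")))
  invisible(x)
}

#' @method glance msf_denoiser
#' @export
glance.msf_denoiser <- function(x, ...) {
  tibble::tibble(k = x$k, n_peaks = length(x$d), noise_model = x$noise_model,
                 snr_k = x$eigenvalues[x$k], snr_1 = x$eigenvalues[1])
}

#' @method tidy msf_denoiser
#' @export
tidy.msf_denoiser <- function(x, ...) {
  tibble::tibble(factor = seq_len(x$k), eigenvalue = x$eigenvalues)
}

#' Denoise a count matrix or cube with a fitted denoiser
#'
#' Projects the whitened, centered data onto the retained loadings,
#' reconstructs, un-centers, un-whitens and clips negative values to zero.
#' The per-peak mean bias introduced by clipping is recorded in the
#' `clip_bias` attribute.
#'
#' @param X Matrix (voxels x peaks) or [sims_cube()], same peak set the
#'   model was fitted on.
#' @param model An `msf_denoiser` from [fit_msf()].
#' @param shrink With `shrink = TRUE`, each retained component is weighted
#'   by its signal share `(lambda - 1) / lambda` instead of 1. In the
#'   whitened metric pure counting noise contributes unit variance per
#'   direction, so a component with eigenvalue `lambda` carries a noise
#'   fraction `1 / lambda`; plain projection (`shrink = FALSE`, the
#'   default, which is the exact identity at `k = n_peaks`) passes that
#'   noise straight into the reconstruction. Shrinkage suppresses
#'   near-unit-eigenvalue components almost entirely while leaving strong
#'   signal components untouched, and is the pipeline default.
#' @return Same shape as the input (matrix in, matrix out; cube in, cube
#'   out), non-negative, with attribute `clip_bias`.
#' @export
denoise <- function(X, model, shrink = FALSE) {
  stopifnot(inherits(model, "msf_denoiser"))
  cube <- NULL
  if (inherits(X, "sims_cube")) {
    cube <- X
    X <- unfold_cube(cube)$X
  }
  if (ncol(X) != length(model$d)) abort("peak set does not match the fitted model")
  w <- 1 / sqrt(model$d)
  Xh <- sweep(X, 2, w, "*")
  ctr <- if (model$center) colMeans(Xh) else rep(0, ncol(X))
  Xh <- sweep(Xh, 2, ctr, "-")
  P <- Xh %*% model$V                 # n x k projection
  rm(Xh)
  gc(verbose = FALSE)
  if (shrink) {
    P <- sweep(P, 2, pmax(0, (model$eigenvalues - 1) / model$eigenvalues),
               "*")
  }
  Xh <- P %*% t(model$V)
  Xh <- sweep(Xh, 2, ctr, "+")
  Xh <- sweep(Xh, 2, w, "/")
  pre_mean <- colMeans(Xh)
  Xh[Xh < 0] <- 0
  bias <- colMeans(Xh) - pre_mean
  if (!is.null(cube)) {
    out <- fold_matrix(Xh, dim(cube$counts)[1:3], cube$peaks,
                       cube$pixel_size_um,
                       provenance = paste0(cube$provenance, sprintf(
                         " | msf denoised (k = %d, %s)", model$k,
                         model$noise_model)))
    attr(out, "clip_bias") <- bias
    return(out)
  }
  attr(Xh, "clip_bias") <- bias
  Xh
}

#' Validate a denoised image against the raw data
#'
#' Three per-peak contracts certify that low-rank denoising preserved the
#' analyte signal:
#' * `F_j` — the residual mean square of peak j over the voxels, divided by
#'   its noise variance estimate, referred to the CDF of an
#'   F(n - k, Inf) distribution (the Poisson variance is treated as known).
#'   Values below the critical probability (0.99 by default in pipeline
#'   checks) mean "no lack of fit at the 1% level".
#' * `R_j^2` — squared Pearson correlation between the layer-by-layer means
#'   of the denoised and raw signal.
#' * Per-class relative deviation — for each segmented class volume,
#'   `|mean denoised - mean raw| / mean raw`.
#'
#' @param X Raw matrix or cube.
#' @param Xhat Denoised matrix or cube of the same geometry.
#' @param model The `msf_denoiser` used.
#' @param layer_index Integer layer per voxel row; inferred automatically
#'   when `X` is a cube.
#' @param class_map Optional per-voxel class labels (array or vector
#'   aligned with the unfolded rows) for the class-deviation statistic.
#' @param peaks Labels of peaks to validate; default all.
#' @return A `denoise_validation` object: list of tibbles `peak_stats`
#'   (`label`, `F_j`, `R_j2`, `undefined`) and `class_stats` (`label`,
#'   `class`, `mean_raw`, `mean_denoised`, `deviation`).
#' @export
validate_denoise <- function(X, Xhat, model, layer_index = NULL,
                             class_map = NULL, peaks = NULL) {
  if (inherits(X, "sims_cube")) {
    layer_index <- layer_index %||% rep(seq_len(dim(X$counts)[1]),
                                        each = prod(dim(X$counts)[2:3]))
    X <- unfold_cube(X)$X
  }
  if (inherits(Xhat, "sims_cube")) Xhat <- unfold_cube(Xhat)$X
  if (!identical(dim(X), dim(Xhat))) abort("raw and denoised shapes differ")
  if (is.null(layer_index)) abort("layer_index is required for matrix input")
  labels <- colnames(X) %||% sprintf("p%d", seq_len(ncol(X)))
  sel <- if (is.null(peaks)) seq_len(ncol(X)) else match(peaks, labels)
  if (anyNA(sel)) abort("requested peaks not present")
  n <- nrow(X)
  df1 <- n - model$k
  res_ms <- colMeans((X[, sel, drop = FALSE] - Xhat[, sel, drop = FALSE])^2) *
    n / df1
  F_j <- pf(res_ms / model$d[sel], df1 = df1, df2 = Inf)
  lr_raw <- rowsum(X[, sel, drop = FALSE], layer_index)
  lr_hat <- rowsum(Xhat[, sel, drop = FALSE], layer_index)
  R_j2 <- vapply(seq_along(sel), function(i) {
    a <- lr_raw[, i]; b <- lr_hat[, i]
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)^2
  }, numeric(1))
  peak_stats <- tibble::tibble(label = labels[sel], F_j = F_j, R_j2 = R_j2,
                               undefined = is.na(R_j2))
  class_stats <- NULL
  if (!is.null(class_map)) {
    cls <- if (is.array(class_map) && length(dim(class_map)) == 3) {
      unfold_map(class_map)
    } else {
      as.vector(class_map)
    }
    if (length(cls) != n) abort("class_map is not aligned with the voxel rows")
    cm_raw <- rowsum(X[, sel, drop = FALSE], cls)
    cm_hat <- rowsum(Xhat[, sel, drop = FALSE], cls)
    nv <- as.vector(table(cls)[rownames(cm_raw)])
    class_stats <- purrr::map_dfr(seq_along(sel), function(i) {
      mr <- cm_raw[, i] / nv
      mh <- cm_hat[, i] / nv
      tibble::tibble(label = labels[sel][i], class = rownames(cm_raw),
                     n_voxels = nv, raw_counts = cm_raw[, i],
                     mean_raw = mr, mean_denoised = mh,
                     deviation = ifelse(mr > 0, abs(mh - mr) / mr, NA_real_))
    })
    if (any(is.na(class_stats$deviation))) {
      warn("classes with zero raw mean flagged as undefined (NA deviation)")
    }
  }
  structure(list(peak_stats = peak_stats, class_stats = class_stats),
            class = "denoise_validation")
}

#' @export
print.denoise_validation <- function(x, ...) {
  cat(sprintf("<denoise_validation> %d peaks; max F_j = %.4f; min R_j2 = %.4f\n",
              nrow(x$peak_stats), max(x$peak_stats$F_j),
              min(x$peak_stats$R_j2, na.rm = TRUE)))
  if (!is.null(x$class_stats)) {
    cat(sprintf("  max class deviation = %.3g\n",
                max(x$class_stats$deviation, na.rm = TRUE)))
  }
  invisible(x)
}
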