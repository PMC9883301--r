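# Multivariate curve resolution by alternating least squares (MCR-ALS)
# with non-negativity on both scores and factor spectra.
#
# Each half-step solves min ||A X - B||_F subject to X >= 0 exactly, by
# enumerating passive (support) sets: for every subset S of the k factors
# the stationary solution restricted to S is computed from the normal
# equations and the best feasible candidate is kept, vectorised over all
# right-hand sides. For the k in use (<= 12) this is exact, fast, and makes
# the ALS objective provably non-increasing (clipping heuristics do not).

# Exact non-negative least squares for many right-hand sides, given the
# Gram matrix AtA (k x k) and cross-products AtB (k x n): solves
# min ||A X - B||_F, X >= 0, column by column. Two routes:
#   nnls_multi  - fast combinatorial active-set (FCNNLS-style): columns
#                 sharing a passive set are solved together, with the exact
#                 Lawson-Hanson step-length inner loop; falls back to
#                 enumeration for any column that exhausts its iteration
#                 safeguard.
#   nnls_enum   - exhaustive enumeration of all 2^k passive sets; O(2^k)
#                 but unconditionally exact, used as the cross-check oracle.

nnls_multi <- function(AtA, AtB) {
  k <- nrow(AtA)
  n <- ncol(AtB)
  ridge <- 1e-12 * max(diag(AtA), 1)
  M <- AtA
  diag(M) <- diag(M) + ridge
  tol_neg <- -1e-10 * max(diag(AtA), 1)
  # grouped solve over the passive sets P (k x m logical); zeros elsewhere
  cssls <- function(B, P = NULL) {
    K <- matrix(0, k, ncol(B))
    if (is.null(P)) {
      K[] <- solve(M, B)
      return(K)
    }
    codes <- as.vector(2^(seq_len(k) - 1) %*% P)
    for (cd in unique(codes)) {
      js <- which(codes == cd)
      S <- which(P[, js[1]])
      if (length(S) == 0) next
      sol <- tryCatch(solve(M[S, S, drop = FALSE], B[S, js, drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sol)) sol <- nnls_enum(AtA[S, S, drop = FALSE],
                                         B[S, js, drop = FALSE])
      K[S, js] <- sol
    }
    K
  }
  K <- cssls(AtB)
  Pset <- K > 0
  K[!Pset] <- 0
  D <- K
  Fset <- which(colSums(Pset) < k) # columns whose unconstrained solution hit bounds
  outer <- 0
  while (length(Fset) > 0) {
    outer <- outer + 1
    if (outer > 10 * k) { # safeguard: finish stragglers exactly
      K[, Fset] <- nnls_enum(AtA, AtB[, Fset, drop = FALSE])
      break
    }
    K[, Fset] <- cssls(AtB[, Fset, drop = FALSE], Pset[, Fset, drop = FALSE])
    Hset <- Fset[.colSums(K[, Fset, drop = FALSE] < tol_neg, k, length(Fset)) > 0]
    inner <- 0
    while (length(Hset) > 0) {
      inner <- inner + 1
      if (inner > 10 * k) {
        K[, Hset] <- nnls_enum(AtA, AtB[, Hset, drop = FALSE])
        Pset[, Hset] <- K[, Hset, drop = FALSE] > 0
        D[, Hset] <- K[, Hset, drop = FALSE]
        break
      }
      m <- length(Hset)
      KH <- K[, Hset, drop = FALSE]
      DH <- D[, Hset, drop = FALSE]
      PH <- Pset[, Hset, drop = FALSE]
      alpha <- matrix(Inf, k, m)
      neg <- PH & KH < tol_neg
      alpha[neg] <- DH[neg] / (DH[neg] - KH[neg])
      amin <- apply(alpha, 2, min)
      mi <- max.col(-t(alpha), ties.method = "first")
      DH <- DH - rep(pmin(amin, 1), each = k) * (DH - KH)
      DH[cbind(mi, seq_len(m))] <- 0
      PH[cbind(mi, seq_len(m))] <- FALSE
      D[, Hset] <- DH
      Pset[, Hset] <- PH
      K[, Hset] <- cssls(AtB[, Hset, drop = FALSE], PH)
      Hset <- Hset[.colSums(K[, Hset, drop = FALSE] < tol_neg, k, m) > 0]
    }
    # optimality: every constrained variable must have non-positive gradient
    W <- AtB[, Fset, drop = FALSE] - M %*% K[, Fset, drop = FALSE]
    W[Pset[, Fset, drop = FALSE]] <- -Inf
    mx <- apply(W, 2, max)
    not_done <- mx > -tol_neg
    if (any(not_done)) {
      js <- Fset[not_done]
      add <- max.col(t(W[, not_done, drop = FALSE]), ties.method = "first")
      Pset[cbind(add, js)] <- TRUE
      D[, js] <- K[, js, drop = FALSE]
    }
    Fset <- Fset[not_done]
  }
  K[K < 0] <- 0
  K
}

nnls_enum <- function(AtA, AtB) {
  k <- nrow(AtA)
  if (k > 14) abort("nnls_multi supports at most 14 factors")
  n <- ncol(AtB)
  ridge <- 1e-12 * max(diag(AtA), 1)
  best_obj <- rep(0, n)        # objective reduction of x = 0 is 0
  best_bits <- integer(n)      # winning passive set per column
  for (bits in seq_len(2^k - 1)) {
    S <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    M <- AtA[S, S, drop = FALSE]
    diag(M) <- diag(M) + ridge
    cand <- tryCatch(solve(M, AtB[S, , drop = FALSE]), error = function(e) NULL)
    if (is.null(cand)) next
    feas <- .colSums(cand >= 0, length(S), n) == length(S)
    if (!any(feas)) next
    # at a stationary point x' AtA x = x' Atb, so the objective reduction
    # 2 x'Atb - x'AtA x collapses to x'Atb
    red <- .colSums(cand * AtB[S, , drop = FALSE], length(S), n)
    upd <- feas & red > best_obj + 1e-12 * (abs(best_obj) + 1)
    if (any(upd)) {
      best_obj[upd] <- red[upd]
      best_bits[upd] <- bits
    }
  }
  X <- matrix(0, k, n)
  for (bits in unique(best_bits[best_bits > 0])) {
    cols <- which(best_bits == bits)
    S <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    M <- AtA[S, S, drop = FALSE]
    diag(M) <- diag(M) + ridge
    X[S, cols] <- solve(M, AtB[S, cols, drop = FALSE])
  }
  X
}

#' Fit a non-negative MCR-ALS factor model
#'
#' Alternating exact non-negative least squares on the scores `C`
#' (n_voxels x k) and factor spectra `S` (k x n_peaks), minimising
#' `||X - C S||_F`. With `weighting = "poisson"` the data are pre-scaled by
#' `rowsum^(-1/2)` and `colmean^(-1/2)` (a Poisson variance-stabilising
#' whitening) before fitting and the factors are unscaled on output.
#' After convergence each factor spectrum is normalized to unit maximum
#' (the scores absorb the scale, so the reconstruction `C S` is unchanged).
#'
#' @param X Non-negative matrix, voxels x peaks (see [unfold_cube()]), or a
#'   [sims_cube()].
#' @param k Number of factors (default 6: water, live cells,
#'   inactive-organic, substrate, detector nonlinearity, other).
#' @param init `"purest_variable"` (deterministic contrast-based variable
#'   selection, the default) or `"random"`.
#' @param seed Seed for `init = "random"`.
#' @param tol Relative change in lack of fit below which iteration stops
#'   (default 1e-6).
#' @param max_iter Maximum ALS iterations (default 200).
#' @param weighting `"none"` or `"poisson"`.
#' @param subsample When the number of voxels exceeds this bound, the
#'   alternating iterations estimate the factor spectra on a deterministic
#'   evenly strided subset of this many voxel rows, and the full score
#'   matrix is computed in one final exact non-negative solve against the
#'   converged spectra. NULL (default) fits on all rows.
#' @return An `mcr_model`: list with `C`, `S`, `k`, `lof_trajectory`
#'   (percent lack of fit per iteration, non-increasing), `n_iter`,
#'   `converged`, `peaks` (labels), `init`, `weighting`, `seed`.
#' @export
fit_mcr <- function(X, k = 6, init = c("purest_variable", "random"),
                    seed = NULL, tol = 1e-6, max_iter = 200,
                    weighting = c("none", "poisson"), subsample = NULL) {
  init <- match.arg(init)
  weighting <- match.arg(weighting)
  if (inherits(X, "sims_cube")) X <- unfold_cube(X)$X
  if (any(X < 0)) abort("X must be non-negative")
  if (k < 1 || k > min(dim(X))) abort("k must satisfy 1 <= k <= min(dim(X))")
  labels <- colnames(X) %||% sprintf("p%d", seq_len(ncol(X)))
  sub_idx <- NULL
  if (!is.null(subsample) && nrow(X) > subsample) {
    # evenly strided rows cover the volume uniformly in (z, y, x) order and
    # keep the fit bit-reproducible without touching the RNG
    sub_idx <- unique(round(seq(1, nrow(X), length.out = subsample)))
  }
  if (weighting == "poisson") {
    rw <- 1 / sqrt(pmax(rowSums(X), 1))
    cw <- 1 / sqrt(pmax(colMeans(X), 1e-3))
    Xw <- X * rw
    Xw <- sweep(Xw, 2, cw, "*")
    gc(verbose = FALSE)
  } else {
    rw <- NULL
    cw <- NULL
    Xw <- X
  }
  Xfull <- Xw
  if (!is.null(sub_idx)) Xw <- Xw[sub_idx, , drop = FALSE]
  C <- switch(init,
    purest_variable = {
      sel <- purest_variables(Xw, k)
      pmax(Xw[, sel, drop = FALSE], 0) + 1e-9
    },
    random = with_seed(seed, matrix(runif(nrow(Xw) * k), ncol = k))
  )
  total_ss <- sum(Xw^2)
  lof <- numeric(0)
  prev <- Inf
  converged <- FALSE
  S <- NULL
  for (it in seq_len(max_iter)) {
    S <- nnls_multi(crossprod(C), crossprod(C, Xw))
    # guard against dead factors (all-zero spectra)
    dead <- rowSums(S) == 0
    if (any(dead)) S[dead, ] <- 1e-9
    XSt <- Xw %*% t(S)                      # n_voxels x k
    SSt <- tcrossprod(S)                    # k x k
    Ct <- nnls_multi(SSt, t(XSt))
    C <- t(Ct)
    res_ss <- total_ss - 2 * sum(C * XSt) + sum(tcrossprod(Ct) * SSt)
    cur <- 100 * sqrt(max(res_ss, 0) / total_ss)
    lof <- c(lof, cur)
    # slack: relative term for regular fits, absolute floor (1e-5 percent
    # points) for exact-fit cases where res_ss is pure cancellation noise
    if (it > 1 && cur > lof[it - 1] + 1e-8 * (lof[it - 1] + 1) + 1e-5) {
      warn(sprintf("ALS objective increased at iteration %d (%.3g -> %.3g)",
                   it, lof[it - 1], cur))
    }
    if (is.finite(prev) && abs(prev - cur) <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (!is.null(sub_idx)) {
    # one exact non-negative solve for the scores of every voxel
    XSt <- Xfull %*% t(S)
    C <- t(nnls_multi(tcrossprod(S), t(XSt)))
  }
  if (weighting == "poisson") {
    C <- C / rw
    S <- sweep(S, 2, cw, "/")
  }
  # fix scale indeterminacy: unit-maximum factor spectra
  sm <- apply(S, 1, max)
  sm[sm == 0] <- 1
  S <- S / sm
  C <- sweep(C, 2, sm, "*")
  colnames(S) <- labels
  structure(list(C = C, S = S, k = k, lof_trajectory = lof,
                 n_iter = length(lof), converged = converged,
                 peaks = labels, init = init, weighting = weighting,
                 seed = seed),
            class = "mcr_model")
}

# SIMPLISMA-style purest-variable selection: greedily pick the k variables
# with the highest purity (sd / (mean + offset)), discounting variables
# correlated with those already chosen.
purest_variables <- function(X, k) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  offset <- 0.01 * max(mu)
  purity <- sdv / (mu + offset)
  norm <- sqrt(mu^2 + (sdv + offset)^2)
  Xn <- sweep(X, 2, pmax(norm, .Machine$double.eps), "/")
  sel <- integer(0)
  w <- purity
  for (i in seq_len(k)) {
    cand <- which.max(w)
    sel <- c(sel, cand)
    if (i < k) {
      r <- abs(crossprod(Xn[, cand], Xn) / nrow(X))
      r <- r / max(r)
      w <- w * (1 - pmin(r[1, ], 1))^2
      w[sel] <- -Inf
    }
  }
  sel
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf("<mcr_model> k = %d, %d voxels x %d peaks, lof %.3f%% after %d iterations (%s)\n",
              x$k, nrow(x$C), ncol(x$S), tail(x$lof_trajectory, 1), x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @method tidy mcr_model
#' @export
tidy.mcr_model <- function(x, ...) {
  tibble::as_tibble(t(x$S)) |>
    setNames(sprintf("factor%d", seq_len(x$k))) |>
    dplyr::mutate(label = x$peaks, .before = 1) |>
    tidyr::pivot_longer(-"label", names_to = "factor", values_to = "intensity")
}

#' @method glance mcr_model
#' @export
glance.mcr_model <- function(x, ...) {
  tibble::tibble(k = x$k, n_iter = x$n_iter, converged = x$converged,
                 lof = tail(x$lof_trajectory, 1), init = x$init,
                 weighting = x$weighting)
}

#' Assign semantic roles to MCR factors
#'
#' Maps factors to the roles `substrate`, `live_marker`, `cell_organic` and
#' `water` from the share of the corresponding marker channels in each
#' (unit-maximum) factor spectrum. Roles are assigned greedily in that
#' order — each role goes to the unassigned factor with the largest marker
#' share, ties broken by larger total score mass — and factors left over
#' are labelled `other` (these absorb detector-nonlinearity and background
#' variation). A role whose marker share is zero in every remaining factor
#' is reported as unassigned.
#'
#' @param model An `mcr_model`.
#' @param peaks The peak list the model was fitted on (for the `species`
#'   column), default [default_peaklist()].
#' @param marker_peaks Named list of character vectors overriding the
#'   marker channels per role.
#' @return A tibble with columns `factor`, `role`, `share`; attribute
#'   `unassigned` lists roles that could not be assigned.
#' @export
assign_factors <- function(model, peaks = default_peaklist(),
                           marker_peaks = NULL) {
  stopifnot(inherits(model, "mcr_model"))
  lab <- model$peaks
  default_markers <- list(
    substrate = peaks$label[peaks$species == "substrate_Al"],
    live_marker = peaks$label[peaks$species %in% c("salt_K", "salt_Na", "salt_Ca")],
    cell_organic = peaks$label[peaks$species == "organic"],
    water = peaks$label[peaks$species == "water"]
  )
  markers <- modifyList(default_markers, marker_peaks %||% list())
  if (model$k < length(markers)) {
    abort(sprintf("k = %d is smaller than the %d requested roles",
                  model$k, length(markers)))
  }
  tot <- rowSums(model$S)
  tot[tot == 0] <- .Machine$double.eps
  mass <- colSums(model$C)
  role <- rep("other", model$k)
  unassigned <- character(0)
  share_rec <- rep(NA_real_, model$k)
  for (r in names(markers)) {
    idx <- match(intersect(markers[[r]], lab), lab)
    if (length(idx) == 0) {
      abort(sprintf("marker peaks for role '%s' are absent from the peak list", r))
    }
    share <- rowSums(model$S[, idx, drop = FALSE]) / tot
    share[role != "other"] <- -Inf
    if (max(share) <= 0) {
      unassigned <- c(unassigned, r)
      inform(sprintf("role '%s': no factor carries its marker channels; left unassigned", r))
      next
    }
    best <- which(share == max(share))
    if (length(best) > 1) best <- best[which.max(mass[best])]
    role[best] <- r
    share_rec[best] <- share[best]
  }
  out <- tibble::tibble(factor = seq_len(model$k), role = role,
                        share = share_rec)
  attr(out, "unassigned") <- unassigned
  out
}
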