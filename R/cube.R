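# The IonImageCube container: a 4-D non-negative count array indexed
# (layer z, row y, col x, peak) plus pixel size, peak list and provenance.
# Layer 1 is the first analysis cycle, i.e. the outermost surface; the base
# of the biofilm sits at the highest layer index. The z axis is in sputter
# cycles and is not depth-calibrated.

#' Construct an ion-image cube
#'
#' @param counts 4-D non-negative array with dimensions
#'   (layers, rows, cols, peaks). Layer 1 is the first-acquired (outermost)
#'   surface.
#' @param peaks Peak-list tibble (see [peaklist()]); its length must match
#'   the fourth dimension of `counts`.
#' @param pixel_size_um Lateral pixel size in micrometres.
#' @param provenance Free-text history of the cube.
#' @return An object of class `sims_cube`.
#' @export
sims_cube <- function(counts, peaks, pixel_size_um = 1, provenance = "") {
  if (length(dim(counts)) != 4) abort("counts must be a 4-D array (z, y, x, peak)")
  if (any(dim(counts) == 0)) abort("empty cube: all dimensions must be positive")
  stop_if_negative(counts)
  validate_peaklist(peaks)
  if (dim(counts)[4] != nrow(peaks)) {
    abort(sprintf("last axis length (%d) must equal number of peaks (%d)",
                  dim(counts)[4], nrow(peaks)))
  }
  structure(
    list(counts = counts, peaks = peaks,
         pixel_size_um = as.numeric(pixel_size_um),
         provenance = as.character(provenance)),
    class = "sims_cube"
  )
}

#' @export
print.sims_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<sims_cube> %d layers x %d x %d pixels x %d peaks\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  pixel size: %.3g um; total counts: %.6g\n",
              x$pixel_size_um, sum(x$counts)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
dim.sims_cube <- function(x) dim(x$counts)

cube_nlayers <- function(cube) dim(cube$counts)[1]

#' Total-ion summed spectrum of a cube
#'
#' Sums counts over all voxels per peak, the stick-spectrum analogue used
#' for reporting and peak-recovery checks.
#'
#' @param cube A [sims_cube()].
#' @return A tibble with columns `label`, `center_mz`, `counts`.
#' @export
cube_total_spectrum <- function(cube) {
  tot <- colSums(unfold_cube(cube)$X)
  tibble::tibble(label = cube$peaks$label,
                 center_mz = cube$peaks$center_mz,
                 counts = tot)
}

#' Down-bin a cube by summing over voxel blocks
#'
#' Counts are summed over non-overlapping `bz` x `by` x `bx` blocks;
#' trailing partial blocks are summed as smaller blocks, so the total ion
#' count is conserved exactly.
#'
#' @param cube A [sims_cube()].
#' @param bz,by,bx Integer bin factors per axis (>= 1, at most the axis
#'   length).
#' @return A down-binned `sims_cube`.
#' @export
#' @examples
#' cube <- sims_cube(array(1, c(2, 2, 2, 1)),
#'                   peaklist("p", 100, 99.9, 100.1))
#' dim(downbin(cube, 2, 2, 2))
downbin <- function(cube, bz = 2, by = 2, bx = 2) {
  stopifnot(inherits(cube, "sims_cube"))
  b <- c(bz, by, bx)
  if (any(b < 1) || any(b != round(b))) abort("bin factors must be integers >= 1")
  d <- dim(cube$counts)
  if (any(b > d[1:3])) abort("bin factor exceeds axis length")
  a <- cube$counts
  for (axis in 1:3) {
    a <- bin_axis(a, axis, b[axis])
  }
  sims_cube(a, cube$peaks, cube$pixel_size_um,
            provenance = paste0(cube$provenance, sprintf(
              " | downbin %dx%dx%d", bz, by, bx)))
}

# Sum an array over groups of size b along one axis (trailing partial group
# kept). Works by rotating the target axis to the front and using rowsum.
bin_axis <- function(a, axis, b) {
  if (b == 1) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(a, perm)
  da <- dim(a)
  grp <- ceiling(seq_len(da[1]) / b)
  m <- matrix(a, nrow = da[1])
  m <- rowsum(m, grp, reorder = TRUE)
  dim(m) <- c(nrow(m), da[-1])
  aperm(m, order(perm))
}

#' Unfold a cube into a voxels-by-peaks matrix
#'
#' Rows are ordered lexicographically by (z, y, x) with x varying fastest:
#' the 1-based row of voxel (z, y, x) is
#' `(z - 1) * ny * nx + (y - 1) * nx + x`. [fold_matrix()] inverts the
#' operation exactly.
#'
#' @param cube A [sims_cube()].
#' @return A list with elements `X` (matrix, n_voxels x n_peaks) and `dims`
#'   (the cube's z, y, x extents).
#' @export
unfold_cube <- function(cube) {
  stopifnot(inherits(cube, "sims_cube"))
  d <- dim(cube$counts)
  a <- aperm(cube$counts, c(3, 2, 1, 4)) # (x, y, z, p): x fastest in memory
  X <- matrix(a, nrow = d[1] * d[2] * d[3], ncol = d[4])
  colnames(X) <- cube$peaks$label
  list(X = X, dims = d[1:3])
}

#' Fold a voxels-by-peaks matrix back into a cube
#'
#' @param X Matrix in the row order produced by [unfold_cube()].
#' @param dims Integer (nz, ny, nx).
#' @param peaks Peak-list tibble.
#' @param pixel_size_um,provenance Passed to [sims_cube()].
#' @return A `sims_cube`.
#' @export
fold_matrix <- function(X, dims, peaks, pixel_size_um = 1, provenance = "") {
  stopifnot(nrow(X) == prod(dims))
  a <- array(X, dim = c(dims[3], dims[2], dims[1], ncol(X)))
  sims_cube(aperm(a, c(3, 2, 1, 4)), peaks, pixel_size_um, provenance)
}

#' Row index of a voxel in the unfolded matrix
#'
#' @param z,y,x 1-based voxel coordinates.
#' @param dims Integer (nz, ny, nx).
#' @return 1-based row indices.
#' @export
voxel_row <- function(z, y, x, dims) {
  (z - 1) * dims[2] * dims[3] + (y - 1) * dims[3] + x
}

# Convert a per-voxel vector in unfold row order into a (z, y, x) array,
# and back. Counterparts of unfold_cube()/fold_matrix() for label maps.
fold_map <- function(v, dims) {
  aperm(array(v, c(dims[3], dims[2], dims[1])), c(3, 2, 1))
}

unfold_map <- function(a) as.vector(aperm(a, c(3, 2, 1)))

#' Extract one peak channel as a (z, y, x) array
#'
#' @param cube A [sims_cube()].
#' @param peak Peak label.
#' @return 3-D numeric array.
#' @export
peak_channel <- function(cube, peak) {
  p <- peak_index(cube$peaks, peak)
  cube$counts[, , , p, drop = TRUE]
}
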