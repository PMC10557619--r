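#' Regular voxel grid in world (RAS+) millimetre coordinates
#'
#' The grid is axis-aligned. `origin` is the world coordinate of the corner
#' of voxel (0,0,0); voxel `i` (0-based) occupies the half-open box
#' `[origin + i*vox, origin + (i+1)*vox)` along each axis, so its centre is
#' at `origin + (i + 0.5)*vox`.
#'
#' @param dim integer vector of length 3, voxel counts per axis.
#' @param vox numeric vector of length 3, voxel size in mm per axis.
#' @param origin world coordinate (mm) of the corner of the first voxel.
#' @return an object of class `vox_grid`.
#' @export
vox_grid <- function(dim, vox = c(1, 1, 1), origin = c(0, 0, 0)) {
  dim <- as.integer(rep_len(dim, 3L))
  vox <- as.numeric(rep_len(vox, 3L))
  origin <- as.numeric(rep_len(origin, 3L))
  if (any(dim <= 0L)) stop("grid dimensions must be positive")
  if (any(!is.finite(vox)) || any(vox <= 0)) stop("voxel sizes must be positive and finite")
  if (any(!is.finite(origin))) stop("grid origin must be finite")
  structure(list(dim = dim, vox = vox, origin = origin), class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, origin (%g, %g, %g)\n",
              x$dim[1], x$dim[2], x$dim[3], x$vox[1], x$vox[2], x$vox[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel-centre affine of a grid
#'
#' 4x4 matrix mapping 0-based voxel indices (centre convention) to world mm.
#'
#' @param grid a [vox_grid()].
#' @return 4x4 numeric matrix.
#' @export
grid_affine <- function(grid) {
  A <- diag(4)
  diag(A)[1:3] <- grid$vox
  A[1:3, 4] <- grid$origin + 0.5 * grid$vox
  A
}

#' Map world points to 0-based voxel indices
#'
#' Membership uses the half-open convention `[edge, edge + size)`.
#'
#' @param grid a [vox_grid()].
#' @param points n x 3 matrix of world mm coordinates.
#' @return n x 3 integer matrix of 0-based voxel indices.
#' @export
world_to_voxel <- function(grid, points) {
  points <- as_point_matrix(points)
  # the 1e-7 (voxel units) nudge keeps points sitting exactly on a voxel
  # edge on a consistent side under floating-point translation noise
  idx <- floor(sweep(sweep(points, 2, grid$origin), 2, grid$vox, "/") + 1e-7)
  storage.mode(idx) <- "integer"
  idx
}

#' World coordinates of voxel centres
#'
#' @param grid a [vox_grid()].
#' @param idx n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_center <- function(grid, idx) {
  idx <- as_point_matrix(idx)
  sweep(sweep(idx + 0.5, 2, grid$vox, "*"), 2, grid$origin, "+")
}

in_grid <- function(grid, idx) {
  idx[, 1] >= 0L & idx[, 1] < grid$dim[1] &
    idx[, 2] >= 0L & idx[, 2] < grid$dim[2] &
    idx[, 3] >= 0L & idx[, 3] < grid$dim[3]
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  points
}

# linear (1-based) array index from 0-based voxel index triplets
voxel_linear_index <- function(grid, idx) {
  1L + idx[, 1] + grid$dim[1] * (idx[, 2] + grid$dim[2] * idx[, 3])
}
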