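#' Scalar volume on a voxel grid
#'
#' A 3D array of feature values (NaN allowed, e.g. off-ribbon cortical
#' maps) together with its [vox_grid()] and a feature name.
#'
#' @param values 3D numeric array matching `grid$dim`.
#' @param grid a [vox_grid()].
#' @param feature feature name (e.g. "FA", "thickness").
#' @return an object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, feature = "scalar") {
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$dim))
    stop("values array must match grid dimensions")
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid, feature = feature),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  rng <- range(x$values[is.finite(x$values)])
  cat(sprintf("<scalar_volume> '%s', %d x %d x %d, finite range [%.4g, %.4g]\n",
              x$feature, x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
              rng[1], rng[2]))
  invisible(x)
}

#' Write a scalar volume to NIfTI-1
#'
#' The voxel-centre affine of the grid becomes the sform/qform (RAS+).
#'
#' @param volume a [scalar_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$values)
  img <- RNifti::`sform<-`(img, structure(grid_affine(volume$grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a scalar volume from NIfTI-1
#'
#' Requires an axis-aligned RAS+ xform (no rotation), which is what this
#' package writes and what template-space maps typically carry.
#'
#' @param path NIfTI file path.
#' @param feature feature name to attach.
#' @return a [scalar_volume()].
#' @export
read_volume_nifti <- function(path, feature = "scalar") {
  img <- RNifti::readNifti(path)
  A <- RNifti::xform(img)
  rot <- A[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4)
    stop("only axis-aligned RAS+ volumes are supported: ", path)
  vox <- diag(rot)
  if (any(vox <= 0)) stop("non-RAS+ orientation in ", path)
  vals <- array(as.numeric(img), dim = dim(img)[1:3])
  grid <- vox_grid(dim(vals), vox, origin = A[1:3, 4] - 0.5 * vox)
  scalar_volume(vals, grid, feature)
}
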