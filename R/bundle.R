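#' Streamline bundle
#'
#' An ordered set of 3D polylines ("streamlines") in world millimetre
#' coordinates, with a reference voxel grid used for voxelization.
#'
#' @param streamlines list of n_i x 3 numeric matrices (world mm), each with
#'   at least 2 rows and finite coordinates.
#' @param grid a [vox_grid()].
#' @param bundle_id bundle name.
#' @return an object of class `streamline_bundle`.
#' @export
streamline_bundle <- function(streamlines, grid, bundle_id = "bundle") {
  if (!is.list(streamlines) || length(streamlines) == 0)
    stop("streamlines must be a non-empty list of point matrices")
  streamlines <- lapply(seq_along(streamlines), function(i) {
    m <- as_point_matrix(streamlines[[i]])
    if (nrow(m) < 2) stop("streamline ", i, " has fewer than 2 points")
    if (!all(is.finite(m))) stop("streamline ", i, " has non-finite coordinates")
    m
  })
  structure(list(streamlines = streamlines, grid = grid, bundle_id = bundle_id),
            class = "streamline_bundle")
}

#' @export
print.streamline_bundle <- function(x, ...) {
  np <- sum(vapply(x$streamlines, nrow, integer(1)))
  cat(sprintf("<streamline_bundle> '%s': %d streamlines, %d points\n",
              x$bundle_id, length(x$streamlines), np))
  invisible(x)
}

#' Number of streamlines in a bundle
#' @param bundle a [streamline_bundle()].
#' @return integer count.
#' @export
n_streamlines <- function(bundle) length(bundle$streamlines)
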