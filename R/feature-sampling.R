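# Sampling scalar volumes along a bundle: tract-averaged microstructure
# (unweighted mean over occupied voxels) and endpoint-probed cortical
# features (containing-voxel reads at each streamline's two termini,
# averaged per streamline, then across streamlines).

#' Tract-averaged scalar value
#'
#' Voxelizes the bundle into the volume's grid and returns the unweighted
#' mean of the volume over occupied voxels. NaN voxels (e.g. off-ribbon
#' cortical maps) are excluded and the excluded fraction reported.
#'
#' @param bundle a [streamline_bundle()].
#' @param volume a [scalar_volume()].
#' @return list with `value` (feature units), `n_voxels` (finite voxels
#'   used) and `excluded_fraction` (NaN/NA fraction of occupied voxels).
#' @export
tract_average_scalar <- function(bundle, volume) {
  mask <- voxelize_bundle(bundle, grid = volume$grid)
  vals <- volume$values[mask]
  finite <- is.finite(vals)
  if (!any(finite))
    stop("no occupied voxel with a finite value for bundle '",
         bundle$bundle_id, "'")
  list(value = mean(vals[finite]),
       n_voxels = sum(finite),
       excluded_fraction = 1 - sum(finite) / length(vals))
}

#' Endpoint-probed cortical feature
#'
#' Reads the map at the voxel containing each streamline's first and last
#' point, averages the two ends per streamline, and returns the mean across
#' streamlines. A streamline with one NaN end uses the finite end;
#' streamlines with both ends NaN are dropped and counted.
#'
#' @param bundle a [streamline_bundle()].
#' @param cortical_map a [scalar_volume()].
#' @return list with `value`, `n_streamlines_used` and `n_dropped`.
#' @export
endpoint_feature <- function(bundle, cortical_map) {
  g <- cortical_map$grid
  ends <- t(vapply(bundle$streamlines, function(s) {
    idx <- world_to_voxel(g, s[c(1L, nrow(s)), , drop = FALSE])
    if (!all(in_grid(g, idx)))
      stop("streamline endpoint outside the map grid in bundle '",
           bundle$bundle_id, "'")
    cortical_map$values[voxel_linear_index(g, idx)]
  }, numeric(2)))
  per_streamline <- rowMeans(ends, na.rm = TRUE)  # one-sided NaN uses finite side
  kept <- is.finite(per_streamline)
  if (!any(kept))
    stop("all streamlines dropped: both endpoint reads NaN for every streamline")
  list(value = mean(per_streamline[kept]),
       n_streamlines_used = sum(kept),
       n_dropped = sum(!kept))
}
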