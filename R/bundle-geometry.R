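# Macrostructural shape features of a streamline bundle. The ten features
# follow the standard bundle shape-analysis conventions: length and span are
# per-streamline means, curl = length/span, diameter treats the bundle as a
# cylinder of equal volume and length, elongation = length/diameter, volumes
# come from the voxelized occupancy mask, and surface areas count exposed
# voxel faces under 6-connectivity.

#' Arc length of a single streamline
#'
#' Sum of Euclidean segment lengths along the polyline.
#'
#' @param streamline n x 3 matrix of world mm points, n >= 2.
#' @return length in mm.
#' @export
streamline_length <- function(streamline) {
  s <- as_point_matrix(streamline)
  if (nrow(s) < 2) stop("streamline must have at least 2 points")
  d <- diff(s)
  sum(sqrt(rowSums(d * d)))
}

#' Centerline features: length, span and curl
#'
#' `length` is the mean streamline arc length, `span` the mean straight-line
#' distance between each streamline's two endpoints, and
#' `curl = length / span` (>= 1; 1 for perfectly straight bundles). A
#' zero-span (closed-loop) bundle yields `curl = NA` with a warning rather
#' than an infinity.
#'
#' @param bundle a [streamline_bundle()].
#' @return list with `length` (mm), `span` (mm) and `curl` (unitless).
#' @export
centerline_features <- function(bundle) {
  lengths <- vapply(bundle$streamlines, streamline_length, numeric(1))
  spans <- vapply(bundle$streamlines, function(s) {
    sqrt(sum((s[nrow(s), ] - s[1, ])^2))
  }, numeric(1))
  len <- mean(lengths)
  span <- mean(spans)
  if (span <= 1e-9 * max(len, 1)) {
    warning("bundle span is zero (closed loop); curl undefined")
    curl <- NA_real_
  } else {
    curl <- len / span
  }
  list(length = len, span = span, curl = curl)
}

densify_streamline <- function(s, max_step) {
  d <- diff(s)
  seg <- sqrt(rowSums(d * d))
  # n_sub pieces per segment so the resulting spacing is strictly < max_step
  n_sub <- as.integer(floor(seg / max_step)) + 1L
  if (all(n_sub == 1L)) return(s)
  idx <- rep(seq_along(seg), n_sub)
  t <- (sequence(n_sub) - 1) / n_sub[idx]
  rbind(s[idx, , drop = FALSE] + t * d[idx, , drop = FALSE],
        s[nrow(s), , drop = FALSE])
}

#' Binary occupancy mask of a bundle on its grid
#'
#' A voxel is occupied iff at least one streamline vertex maps into it,
#' after densifying segments so consecutive vertices are less than half a
#' voxel apart.
#'
#' @param bundle a [streamline_bundle()].
#' @param grid grid to voxelize on; defaults to the bundle's own.
#' @param points `"all"` for full streamlines, `"endpoints"` for first and
#'   last vertices only, or an n x 3 matrix of world points.
#' @return logical 3D array of dimension `grid$dim`.
#' @export
voxelize_bundle <- function(bundle, grid = bundle$grid, points = "all") {
  if (is.matrix(points)) {
    pt_sets <- list(points)
  } else if (identical(points, "endpoints")) {
    pt_sets <- lapply(bundle$streamlines, function(s)
      s[c(1L, nrow(s)), , drop = FALSE])
  } else {
    max_step <- min(grid$vox) / 2
    pt_sets <- lapply(bundle$streamlines, densify_streamline, max_step = max_step)
  }
  mask <- array(FALSE, grid$dim)
  sid <- rep(seq_along(pt_sets), vapply(pt_sets, nrow, integer(1)))
  pts <- do.call(rbind, pt_sets)
  idx <- world_to_voxel(grid, pts)
  ok <- in_grid(grid, idx)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop("streamline ", sid[bad], " has points outside the grid (first at world ",
         paste(signif(pts[bad, ], 5), collapse = ", "), ")")
  }
  mask[voxel_linear_index(grid, idx)] <- TRUE
  mask
}

#' Bundle volume and endpoint volume
#'
#' Occupied-voxel count times voxel volume; the endpoint volume uses only
#' the first and last vertex of every streamline.
#'
#' @param bundle a [streamline_bundle()].
#' @return list with `volume` and `endpoint_volume`, both mm^3.
#' @export
bundle_volumes <- function(bundle) {
  vv <- prod(bundle$grid$vox)
  list(volume = sum(voxelize_bundle(bundle)) * vv,
       endpoint_volume = sum(voxelize_bundle(bundle, points = "endpoints")) * vv)
}

#' Cylinder-approximation diameter and elongation
#'
#' Treats the bundle as a cylinder of the given volume and length:
#' `diameter = 2 * sqrt(volume / (pi * length))`; `elongation = length / diameter`.
#'
#' @param volume bundle volume, mm^3 (> 0).
#' @param length bundle length, mm (> 0).
#' @return list with `diameter` (mm) and `elongation` (unitless).
#' @export
cylinder_features <- function(volume, length) {
  if (!is.finite(volume) || volume <= 0) stop("volume must be positive")
  if (!is.finite(length) || length <= 0) stop("length must be positive")
  diameter <- 2 * sqrt(volume / (pi * length))
  list(diameter = diameter, elongation = length / diameter)
}

#' Consistent head/tail orientation of a bundle's endpoints
#'
#' Streamlines are reoriented so every "first" point lies in one end
#' cluster. The head is the end whose centroid has the smaller coordinate
#' along the dominant displacement axis (the axis with the largest mean
#' absolute endpoint-to-endpoint displacement), i.e. the most
#' left/posterior/inferior end in RAS, with ties broken x then y then z.
#' The result is deterministic and invariant to stored point order.
#'
#' @param bundle a [streamline_bundle()].
#' @return list with `flip` (logical per streamline: TRUE if reversed),
#'   `head_points` and `tail_points` (matrices of oriented first/last
#'   endpoints), and `axis` (dominant axis index).
#' @export
split_head_tail <- function(bundle) {
  firsts <- t(vapply(bundle$streamlines, function(s) s[1, ], numeric(3)))
  lasts <- t(vapply(bundle$streamlines, function(s) s[nrow(s), ], numeric(3)))
  disp <- lasts - firsts
  mean_abs <- colMeans(abs(disp))
  if (max(mean_abs) < 1e-9)
    stop("degenerate bundle: endpoint span is approximately zero")
  axis_order <- order(-mean_abs, seq_len(3))  # dominant first, ties x<y<z
  flip <- rep(FALSE, nrow(disp))
  # orient each streamline by the first axis (in dominance order) on which
  # it has nonzero displacement
  for (i in seq_len(nrow(disp))) {
    for (ax in axis_order) {
      if (abs(disp[i, ax]) > 1e-12) {
        flip[i] <- disp[i, ax] < 0
        break
      }
    }
  }
  head_points <- ifelse(matrix(flip, nrow(firsts), 3), lasts, firsts)
  tail_points <- ifelse(matrix(flip, nrow(firsts), 3), firsts, lasts)
  list(flip = flip, head_points = head_points, tail_points = tail_points,
       axis = axis_order[1])
}

exposed_face_area <- function(mask, vox) {
  d <- dim(mask)
  face_area <- c(vox[2] * vox[3], vox[1] * vox[3], vox[1] * vox[2])
  total <- 0
  for (ax in 1:3) {
    # count occupied->unoccupied transitions along axis ax, both directions
    n <- d[ax]
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(mask, perm)
    dm <- dim(m)
    shifted_lo <- array(FALSE, dm); shifted_hi <- array(FALSE, dm)
    if (n > 1) {
      shifted_lo[2:n, , ] <- m[1:(n - 1), , ]  # neighbour below
      shifted_hi[1:(n - 1), , ] <- m[2:n, , ]  # neighbour above
    }
    exposed <- sum(m & !shifted_lo) + sum(m & !shifted_hi)
    total <- total + exposed * face_area[ax]
  }
  total
}

#' Bundle surface areas from exposed voxel faces
#'
#' Total surface area is the summed area of occupied-voxel faces adjacent
#' to unoccupied voxels (6-connectivity). Head and tail surface areas apply
#' the same computation to the occupancy masks of the head and tail
#' endpoint voxels from [split_head_tail()].
#'
#' @param bundle a [streamline_bundle()].
#' @return list with `surface_area`, `surface_area_head`,
#'   `surface_area_tail`, all mm^2.
#' @export
surface_areas <- function(bundle) {
  g <- bundle$grid
  mask <- voxelize_bundle(bundle)
  total <- exposed_face_area(mask, g$vox)
  ht <- tryCatch(split_head_tail(bundle), error = function(e) NULL)
  if (is.null(ht)) {
    warning("bundle has no resolvable head/tail orientation; ",
            "head/tail surface areas are NA")
    return(list(surface_area = total, surface_area_head = NA_real_,
                surface_area_tail = NA_real_))
  }
  head_mask <- voxelize_bundle(bundle, points = ht$head_points)
  tail_mask <- voxelize_bundle(bundle, points = ht$tail_points)
  list(surface_area = total,
       surface_area_head = exposed_face_area(head_mask, g$vox),
       surface_area_tail = exposed_face_area(tail_mask, g$vox))
}

#' All ten shape features of a bundle
#'
#' Assembles volume, endpoint volume, length, span, curl, diameter,
#' elongation, total surface area and head/tail surface areas.
#'
#' @param bundle a [streamline_bundle()].
#' @return one-row data.frame with the ten feature columns and `bundle`.
#' @export
compute_shape_features <- function(bundle) {
  cl <- centerline_features(bundle)
  vols <- bundle_volumes(bundle)
  cyl <- cylinder_features(vols$volume, cl$length)
  sa <- surface_areas(bundle)
  data.frame(bundle = bundle$bundle_id,
             volume = vols$volume,
             endpoint_volume = vols$endpoint_volume,
             length = cl$length,
             span = cl$span,
             curl = cl$curl,
             diameter = cyl$diameter,
             elongation = cyl$elongation,
             surface_area = sa$surface_area,
             surface_area_head = sa$surface_area_head,
             surface_area_tail = sa$surface_area_tail,
             stringsAsFactors = FALSE)
}
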