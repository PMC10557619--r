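straight_seg <- function(p0, p1, n = 2) {
  t <- seq(0, 1, length.out = n)
  cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]),
        p0[3] + t * (p1[3] - p0[3]))
}

test_that("streamline arc length matches analytic values", {
  expect_equal(streamline_length(straight_seg(c(0, 0, 0), c(0, 0, 100))), 100)
  bent <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 4, 0))
  expect_equal(streamline_length(bent), 7)
  theta <- seq(0, pi, length.out = 1000)
  semi <- cbind(50 * cos(theta), 0, 50 * sin(theta))
  expect_equal(streamline_length(semi), pi * 50, tolerance = 1e-3)
  expect_error(streamline_length(matrix(0, 1, 3)), "at least 2 points")
})

test_that("centerline features: parallel tube and semicircular arc", {
  g <- vox_grid(c(30, 30, 120), origin = c(-15, -15, -10))
  par_bundle <- streamline_bundle(lapply(0:4, function(i)
    straight_seg(c(i, 0, 0), c(i, 0, 100), 51)), g)
  cl <- centerline_features(par_bundle)
  expect_equal(cl$length, 100)
  expect_equal(cl$span, 100)
  expect_equal(cl$curl, 1)

  arc <- generate_bundle("arc", n_streamlines = 20, radius = 50, angle = pi,
                         seed = 4)
  expect_equal(centerline_features(arc)$curl, pi / 2, tolerance = 0.01)
})

test_that("centerline features agree with an independent re-implementation", {
  b <- generate_bundle("fan", n_streamlines = 25, length = 60, seed = 11)
  cl <- centerline_features(b)
  # brute force: per-streamline loops, no shared code path
  lens <- spans <- numeric(0)
  for (s in b$streamlines) {
    L <- 0
    for (i in 2:nrow(s)) L <- L + sqrt(sum((s[i, ] - s[i - 1, ])^2))
    lens <- c(lens, L)
    spans <- c(spans, sqrt(sum((s[nrow(s), ] - s[1, ])^2)))
  }
  expect_equal(cl$length, mean(lens), tolerance = 1e-9)
  expect_equal(cl$span, mean(spans), tolerance = 1e-9)
  expect_equal(cl$curl, mean(lens) / mean(spans), tolerance = 1e-9)
})

test_that("zero-span bundles flag curl as undefined", {
  g <- vox_grid(c(20, 20, 20), origin = c(-10, -10, -10))
  theta <- seq(0, 2 * pi, length.out = 100)
  loop <- cbind(5 * cos(theta), 5 * sin(theta), 0)
  b <- streamline_bundle(list(loop), g)
  expect_warning(cl <- centerline_features(b), "curl undefined")
  expect_true(is.na(cl$curl))
})

test_that("voxelization enumerates traversed voxels", {
  g <- vox_grid(c(21, 21, 21), origin = c(-0.5, -0.5, -0.5))
  # single vertex at a voxel centre -> one voxel
  one <- streamline_bundle(list(rbind(c(5, 5, 5), c(5, 5, 5))), g)
  expect_equal(sum(voxelize_bundle(one)), 1)
  # 10 mm straight segment through voxel centres -> 11 voxels
  seg <- streamline_bundle(list(straight_seg(c(0, 5, 5), c(10, 5, 5))), g)
  expect_equal(sum(voxelize_bundle(seg)), 11)
  expect_error(streamline_bundle(list(), g), "non-empty")
  outside <- streamline_bundle(list(straight_seg(c(0, 0, 0), c(0, 0, 500))), g)
  expect_error(voxelize_bundle(outside), "outside the grid")
})

test_that("volumes count occupied voxels times voxel volume", {
  g <- vox_grid(c(50, 50, 50), origin = c(-0.5, -0.5, -0.5))
  # vertices at 40 distinct voxel centres
  pts <- cbind(rep(seq(0, 9), 4), rep(seq(0, 3), each = 10), 7)
  b <- streamline_bundle(split.data.frame(pts, rep(1:4, each = 10)), g)
  v <- bundle_volumes(b)
  expect_equal(v$volume, 40)
  one <- streamline_bundle(list(straight_seg(c(0, 5, 5), c(10, 5, 5))), g)
  expect_equal(bundle_volumes(one)$endpoint_volume, 2)
})

test_that("tube volume and diameter approach the analytic cylinder", {
  b <- generate_bundle("straight_tube", n_streamlines = 2000, length = 100,
                       radius = 5, vox = 0.5, seed = 3)
  v <- bundle_volumes(b)
  expect_lt(abs(v$volume - pi * 25 * 100) / (pi * 25 * 100), 0.1)
  cyl <- cylinder_features(v$volume, centerline_features(b)$length)
  expect_lt(abs(cyl$diameter - 10) / 10, 0.1)
})

test_that("cylinder features satisfy their algebraic identities", {
  cf <- cylinder_features(pi * 100, 100)
  expect_equal(cf$diameter, 2)
  expect_equal(cf$elongation, 50)
  expect_equal(cylinder_features(2 * pi * 100, 100)$diameter, 2 * sqrt(2))
  expect_error(cylinder_features(-1, 10), "positive")
  expect_error(cylinder_features(10, 0), "positive")
})

test_that("head/tail split is deterministic and orientation invariant", {
  b <- generate_bundle("straight_tube", n_streamlines = 30, length = 60,
                       seed = 6)
  ht <- split_head_tail(b)
  expect_equal(ht$axis, 3)
  expect_true(all(ht$head_points[, 3] < ht$tail_points[, 3]))
  # reverse half the streamlines: same head/tail point sets
  rev_streamlines <- b$streamlines
  for (i in seq(1, 30, by = 2))
    rev_streamlines[[i]] <- rev_streamlines[[i]][nrow(rev_streamlines[[i]]):1, ]
  b_rev <- streamline_bundle(rev_streamlines, b$grid, b$bundle_id)
  ht_rev <- split_head_tail(b_rev)
  expect_equal(ht_rev$head_points, ht$head_points)
  expect_equal(ht_rev$tail_points, ht$tail_points)
})

test_that("head/tail split matches a 2-means clustering oracle", {
  b <- generate_bundle("fan", n_streamlines = 40, length = 70, spread = 30,
                       seed = 8)
  ht <- split_head_tail(b)
  ends <- rbind(ht$head_points, ht$tail_points)
  km <- stats::kmeans(ends, centers = rbind(colMeans(ht$head_points),
                                            colMeans(ht$tail_points)))
  expect_true(all(km$cluster[1:40] == 1))
  expect_true(all(km$cluster[41:80] == 2))
})

test_that("degenerate bundles cannot be split into head and tail", {
  g <- vox_grid(c(20, 20, 20), origin = c(-10, -10, -10))
  theta <- seq(0, 2 * pi, length.out = 50)
  loop <- cbind(3 * cos(theta), 3 * sin(theta), 0)
  expect_error(split_head_tail(streamline_bundle(list(loop, loop), g)),
               "degenerate")
})

test_that("surface areas count exposed voxel faces", {
  g <- vox_grid(c(20, 20, 20), origin = c(-0.5, -0.5, -0.5))
  one <- streamline_bundle(list(rbind(c(5, 5, 5), c(5, 5, 5))), g)
  expect_warning(sa_one <- surface_areas(one), "head/tail")
  expect_equal(sa_one$surface_area, 6)
  rod <- streamline_bundle(list(straight_seg(c(5, 5, 3), c(5, 5, 12))), g)
  expect_equal(surface_areas(rod)$surface_area, 42)  # 4*10 sides + 2 caps
  domino <- streamline_bundle(list(rbind(c(5, 5, 5), c(6, 5, 5))), g)
  expect_equal(surface_areas(domino)$surface_area, 10)
})

test_that("anisotropic voxels weight faces by their area", {
  g <- vox_grid(c(10, 10, 10), vox = c(1, 2, 3), origin = c(0, 0, 0))
  one <- streamline_bundle(list(rbind(c(4.5, 5, 4.5), c(4.5, 5, 4.5))), g)
  sa <- suppressWarnings(surface_areas(one))
  expect_equal(sa$surface_area, 2 * (2 * 3 + 1 * 3 + 1 * 2))
})

test_that("assembled shape features equal their components", {
  b <- generate_bundle("arc", n_streamlines = 40, radius = 50, angle = pi,
                       seed = 10)
  sf <- compute_shape_features(b)
  expect_equal(sf$curl, pi / 2, tolerance = 0.02)
  cl <- centerline_features(b)
  v <- bundle_volumes(b)
  cyl <- cylinder_features(v$volume, cl$length)
  sa <- surface_areas(b)
  expect_equal(sf$length, cl$length)
  expect_equal(sf$span, cl$span)
  expect_equal(sf$volume, v$volume)
  expect_equal(sf$endpoint_volume, v$endpoint_volume)
  expect_equal(sf$diameter, cyl$diameter)
  expect_equal(sf$elongation, cyl$elongation)
  expect_equal(sf$surface_area, sa$surface_area)
  expect_equal(sf$surface_area_head, sa$surface_area_head)
  expect_equal(sf$surface_area_tail, sa$surface_area_tail)
  expect_lte(sf$endpoint_volume, sf$volume)
  expect_equal(sf$elongation, sf$length / sf$diameter)
  tube <- generate_bundle("straight_tube", n_streamlines = 60, seed = 2)
  expect_equal(compute_shape_features(tube)$curl, 1, tolerance = 0.01)
})

test_that("shape features are invariant to integer-voxel translation and reversal", {
  b <- generate_bundle("fan", n_streamlines = 20, length = 50, seed = 12)
  sf <- compute_shape_features(b)
  # translate streamlines and grid by an integer number of voxels
  shift <- c(3, -2, 5) * b$grid$vox
  b_shift <- streamline_bundle(lapply(b$streamlines, function(s)
    sweep(s, 2, shift, "+")),
    vox_grid(b$grid$dim, b$grid$vox, b$grid$origin + shift), b$bundle_id)
  sf_shift <- compute_shape_features(b_shift)
  for (col in setdiff(names(sf), "bundle"))
    expect_equal(sf_shift[[col]], sf[[col]], tolerance = 1e-6, info = col)
  # reverse every streamline's point order
  b_rev <- streamline_bundle(lapply(b$streamlines, function(s)
    s[nrow(s):1, ]), b$grid, b$bundle_id)
  sf_rev <- compute_shape_features(b_rev)
  for (col in setdiff(names(sf), "bundle"))
    expect_equal(sf_rev[[col]], sf[[col]], tolerance = 1e-9, info = col)
})

test_that("curl never drops below 1 and volume grows monotonically", {
  for (seed in 1:6) {
    shape <- c("straight_tube", "arc", "fan")[(seed %% 3) + 1]
    b <- generate_bundle(shape, n_streamlines = 15, seed = seed)
    expect_gte(centerline_features(b)$curl, 1 - 1e-9)
  }
  b <- generate_bundle("fan", n_streamlines = 30, length = 50, seed = 13)
  vols <- vapply(c(5, 15, 30), function(k) {
    sub <- streamline_bundle(b$streamlines[1:k], b$grid, b$bundle_id)
    bundle_volumes(sub)$volume
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})
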