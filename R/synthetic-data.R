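# Synthetic cohort generator. Emulates a four-cohort age-partitioned study
# (infant / development / young-adult / aging) with smooth nonlinear
# ground-truth trajectories per bundle x feature, an additive acquisition
# offset confined to the young-adult cohort, an additive sex effect,
# Gaussian residual noise, and optional repeated sessions for infant
# subjects. Every generator is deterministic given its seed.

#' Ground-truth trajectory record for one bundle x feature
#'
#' @param bundle_id bundle name.
#' @param feature feature name.
#' @param curve_family one of `"poisson_like"` (`c0 + c1*a*exp(-c2*a)`),
#'   `"quadratic"` (`c0 + c1*a + c2*a^2`) or `"spline"` (natural cubic
#'   interpolation through control points).
#' @param params numeric coefficients: `c(c0, c1, c2)` for the closed-form
#'   families, or a list with `ages` and `values` for `"spline"`.
#' @param ya_offset additive offset applied only to young-adult rows
#'   (feature units).
#' @param noise_sd residual standard deviation (>= 0, feature units).
#' @param sex_effect additive shift applied to female rows (feature units).
#' @return an object of class `truth_record`.
#' @export
truth_record <- function(bundle_id, feature,
                         curve_family = c("poisson_like", "quadratic", "spline"),
                         params, ya_offset = 0, noise_sd = 0, sex_effect = 0) {
  curve_family <- match.arg(curve_family)
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.finite(ya_offset) || !is.finite(sex_effect))
    stop("ya_offset and sex_effect must be finite")
  if (curve_family == "spline") {
    if (!is.list(params) || is.null(params$ages) || is.null(params$values) ||
        length(params$ages) != length(params$values) || length(params$ages) < 2)
      stop("spline params must be a list with matching 'ages' and 'values'")
  } else {
    if (!is.numeric(params) || length(params) != 3 || any(!is.finite(params)))
      stop(curve_family, " params must be 3 finite coefficients c(c0, c1, c2)")
  }
  rec <- structure(list(bundle_id = bundle_id, feature = feature,
                        curve_family = curve_family, params = params,
                        ya_offset = ya_offset, noise_sd = noise_sd,
                        sex_effect = sex_effect),
                   class = "truth_record")
  probe <- eval_truth_curve(rec, seq(0, 100, by = 0.5))
  if (any(!is.finite(probe))) stop("truth curve is not finite on [0, 100] years")
  rec
}

#' Evaluate a truth record's mean curve
#'
#' @param truth a [truth_record()].
#' @param ages ages in years.
#' @return curve values in feature units (no offset, sex effect or noise).
#' @export
eval_truth_curve <- function(truth, ages) {
  p <- truth$params
  switch(truth$curve_family,
         poisson_like = p[1] + p[2] * ages * exp(-p[3] * ages),
         quadratic = p[1] + p[2] * ages + p[3] * ages^2,
         spline = stats::splinefun(p$ages, p$values, method = "natural")(ages))
}

#' Cohort specification
#'
#' Default age bounds follow the four study cohorts: infant 0.03-6.1,
#' development 5.5-21.9, young_adult 22-37, aging 36-100 years.
#'
#' @param cohort one of `"infant"`, `"development"`, `"young_adult"`, `"aging"`.
#' @param age_low,age_high cohort age bounds in years; defaults per cohort.
#' @param n_subjects number of subjects (>= 0).
#' @param sessions_per_subject integer range `c(min, max)`; values > 1 are
#'   only allowed for the (longitudinal) infant cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort = c("infant", "development", "young_adult", "aging"),
                        age_low = NULL, age_high = NULL, n_subjects = 100,
                        sessions_per_subject = c(1, 1)) {
  cohort <- match.arg(cohort)
  bounds <- list(infant = c(0.03, 6.1), development = c(5.5, 21.9),
                 young_adult = c(22, 37), aging = c(36, 100))[[cohort]]
  if (is.null(age_low)) age_low <- bounds[1]
  if (is.null(age_high)) age_high <- bounds[2]
  if (age_low >= age_high) stop("age_low must be below age_high")
  if (!is.finite(n_subjects) || n_subjects < 0)
    stop("n_subjects must be a non-negative count")
  sessions_per_subject <- as.integer(rep_len(sessions_per_subject, 2))
  if (any(sessions_per_subject < 1) ||
      sessions_per_subject[1] > sessions_per_subject[2])
    stop("sessions_per_subject must be an increasing range of counts >= 1")
  if (sessions_per_subject[2] > 1 && cohort != "infant")
    stop("repeated sessions are only supported for the infant cohort")
  structure(list(cohort = cohort, age_low = age_low, age_high = age_high,
                 n_subjects = as.integer(n_subjects),
                 sessions_per_subject = sessions_per_subject),
            class = "cohort_spec")
}

#' Default four-cohort design
#'
#' Desk-scale design: `n_per_cohort` subjects per cohort (default 100),
#' infant subjects longitudinal with 1-3 sessions.
#'
#' @param n_per_cohort subjects per cohort.
#' @param infant_sessions session range for infant subjects.
#' @return list of four [cohort_spec()]s.
#' @export
default_cohorts <- function(n_per_cohort = 100, infant_sessions = c(1, 3)) {
  list(cohort_spec("infant", n_subjects = n_per_cohort,
                   sessions_per_subject = infant_sessions),
       cohort_spec("development", n_subjects = n_per_cohort),
       cohort_spec("young_adult", n_subjects = n_per_cohort),
       cohort_spec("aging", n_subjects = n_per_cohort))
}

#' Full-size cohort design preset
#'
#' Subject counts matching the study's four cohorts (259, 652, 1206, 722
#' subjects; infants with 1-5 sessions).
#'
#' @return list of four [cohort_spec()]s.
#' @export
study_size_cohorts <- function() {
  list(cohort_spec("infant", n_subjects = 259, sessions_per_subject = c(1, 5)),
       cohort_spec("development", n_subjects = 652),
       cohort_spec("young_adult", n_subjects = 1206),
       cohort_spec("aging", n_subjects = 722))
}

#' Generate a synthetic feature table
#'
#' One row per session x bundle, with one column per feature. Ages are
#' drawn uniformly within each cohort's bounds; infant subjects may carry
#' multiple sessions at increasing ages (0.5-1.5 y increments, truncated at
#' the cohort upper bound). Values are
#' `curve(age) + sex_effect*[sex == F] + ya_offset*[cohort == young_adult] + N(0, noise_sd)`.
#'
#' @param truth list of [truth_record()]s (one per bundle x feature).
#' @param cohorts list of [cohort_spec()]s.
#' @param seed integer seed; identical inputs and seed give an identical table.
#' @return list with `table` (data.frame: subject_id, session_id, age, sex,
#'   cohort, bundle, then feature columns) and `truth` (the input records).
#' @export
generate_feature_table <- function(truth, cohorts = default_cohorts(), seed = 1) {
  if (inherits(truth, "truth_record")) truth <- list(truth)
  if (!length(truth) || !all(vapply(truth, inherits, logical(1), "truth_record")))
    stop("truth must be a list of truth_record objects")
  if (inherits(cohorts, "cohort_spec")) cohorts <- list(cohorts)
  if (!all(vapply(cohorts, inherits, logical(1), "cohort_spec")))
    stop("cohorts must be a list of cohort_spec objects")
  set.seed(as.integer(seed))

  sessions <- list()
  for (cs in cohorts) {
    if (cs$n_subjects == 0) next
    sub_ids <- sprintf("%s_%04d", cs$cohort, seq_len(cs$n_subjects))
    sexes <- ifelse(stats::runif(cs$n_subjects) < 0.5, "F", "M")
    base_age <- stats::runif(cs$n_subjects, cs$age_low, cs$age_high)
    n_sess <- if (cs$sessions_per_subject[2] > 1) {
      sample(seq(cs$sessions_per_subject[1], cs$sessions_per_subject[2]),
             cs$n_subjects, replace = TRUE)
    } else rep(1L, cs$n_subjects)
    for (i in seq_len(cs$n_subjects)) {
      ages <- base_age[i]
      if (n_sess[i] > 1) {
        incr <- stats::runif(n_sess[i] - 1, 0.5, 1.5)
        ages <- c(ages, base_age[i] + cumsum(incr))
        ages <- ages[ages <= cs$age_high]  # stay within cohort bounds
      }
      sessions[[length(sessions) + 1L]] <- data.frame(
        subject_id = sub_ids[i],
        session_id = sprintf("ses-%02d", seq_along(ages)),
        age = ages, sex = sexes[i], cohort = cs$cohort,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(sessions)) stop("no subjects in any cohort")
  meta <- do.call(rbind, sessions)

  bundles <- unique(vapply(truth, function(tr) tr$bundle_id, character(1)))
  tab <- meta[rep(seq_len(nrow(meta)), times = length(bundles)), , drop = FALSE]
  tab$bundle <- rep(bundles, each = nrow(meta))
  rownames(tab) <- NULL

  features <- unique(vapply(truth, function(tr) tr$feature, character(1)))
  for (f in features) tab[[f]] <- NA_real_
  is_f <- tab$sex == "F"
  is_ya <- tab$cohort == "young_adult"
  for (tr in truth) {
    rows <- which(tab$bundle == tr$bundle_id)
    mu <- eval_truth_curve(tr, tab$age[rows]) +
      tr$sex_effect * is_f[rows] + tr$ya_offset * is_ya[rows]
    noise <- if (tr$noise_sd > 0) stats::rnorm(length(rows), 0, tr$noise_sd) else 0
    tab[[tr$feature]][rows] <- mu + noise
  }
  list(table = tab, truth = truth)
}

#' Generate a parametric streamline bundle fixture
#'
#' Three analytic geometries with known shape features:
#' * `straight_tube`: parallel polylines of length `length` inside a
#'   cylinder of radius `radius` along +z (first streamline on the axis);
#' * `arc`: concentric circular arcs of radius `radius` and angle `angle`
#'   in the x-z plane, jittered within a tube of radius `tube_radius`;
#' * `fan`: straight streamlines sharing one small end region and spreading
#'   over a width of `2 * spread` at the other end.
#'
#' Vertices are spaced at most half a voxel apart. The bundle is centred in
#' its grid; an explicit grid too small for the geometry is an error.
#'
#' @param shape `"straight_tube"`, `"arc"` or `"fan"`.
#' @param n_streamlines number of streamlines (>= 1).
#' @param length tube/fan length in mm.
#' @param radius tube radius or arc radius, mm.
#' @param angle arc angle in radians.
#' @param tube_radius cross-section radius for `arc`, mm.
#' @param spread half-width of the fan's open end, mm.
#' @param grid a [vox_grid()], or `NULL` to build a fitting 1 mm grid.
#' @param vox voxel size used when `grid` is `NULL`.
#' @param seed integer seed.
#' @return a [streamline_bundle()].
#' @export
generate_bundle <- function(shape = c("straight_tube", "arc", "fan"),
                            n_streamlines = 50, length = 100, radius = 5,
                            angle = pi, tube_radius = 2, spread = 20,
                            grid = NULL, vox = c(1, 1, 1), seed = 1) {
  shape <- match.arg(shape)
  if (n_streamlines < 1) stop("n_streamlines must be >= 1")
  if (length <= 0 || radius <= 0 || tube_radius <= 0 || spread <= 0)
    stop("lengths and radii must be positive")
  set.seed(as.integer(seed))
  vox <- rep_len(as.numeric(vox), 3)
  step <- min(vox) / 2

  disc_offsets <- function(n, r) {
    # first streamline exactly on the axis; rest uniform in the disc
    theta <- stats::runif(n, 0, 2 * pi)
    rad <- r * sqrt(stats::runif(n))
    out <- cbind(rad * cos(theta), rad * sin(theta))
    out[1, ] <- 0
    out
  }

  streamlines <- switch(shape,
    straight_tube = {
      off <- disc_offsets(n_streamlines, radius)
      z <- seq(0, length, by = step)
      if (z[base::length(z)] != length) z <- c(z, length)
      lapply(seq_len(n_streamlines), function(i)
        cbind(off[i, 1], off[i, 2], z))
    },
    arc = {
      off <- disc_offsets(n_streamlines, tube_radius)
      # spacing set by the outermost radius so every streamline obeys it
      n_pts <- max(3L, ceiling((radius + tube_radius) * angle / step) + 1L)
      theta <- seq(0, angle, length.out = n_pts)
      lapply(seq_len(n_streamlines), function(i) {
        r_i <- radius + off[i, 1]
        cbind(r_i * cos(theta), off[i, 2], r_i * sin(theta))
      })
    },
    fan = {
      start <- disc_offsets(n_streamlines, tube_radius)
      end_x <- if (n_streamlines == 1) 0 else
        seq(-spread, spread, length.out = n_streamlines)
      lapply(seq_len(n_streamlines), function(i) {
        p0 <- c(start[i, 1], start[i, 2], 0)
        p1 <- c(end_x[i], 0, length)
        seg <- sqrt(sum((p1 - p0)^2))
        t <- seq(0, 1, length.out = ceiling(seg / step) + 1L)
        cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]),
              p0[3] + t * (p1[3] - p0[3]))
      })
    })

  pts <- do.call(rbind, streamlines)
  if (is.null(grid)) {
    grid <- bounding_grid(streamlines, vox = vox, margin = 5)
  } else {
    lo <- grid$origin
    hi <- grid$origin + grid$dim * grid$vox
    if (any(apply(pts, 2, min) < lo) || any(apply(pts, 2, max) >= hi))
      stop("bundle geometry exceeds the grid extent")
  }
  streamline_bundle(streamlines, grid, bundle_id = shape)
}

#' Generate an analytic scalar volume fixture
#'
#' Fields with known values at every voxel centre: a constant, a linear
#' gradient equal to the world coordinate along one axis, or a two-region
#' split at a world boundary along one axis.
#'
#' @param grid a [vox_grid()].
#' @param field `"constant"`, `"gradient"` or `"two_region"`.
#' @param value constant value (for `"constant"`).
#' @param axis 1, 2 or 3 (x, y, z) for gradient/two_region fields.
#' @param v1,v2 region values: `v1` where the axis coordinate is below
#'   `boundary`, `v2` elsewhere.
#' @param boundary world mm split point for `"two_region"`.
#' @param feature feature name.
#' @return a [scalar_volume()].
#' @export
generate_scalar_volume <- function(grid, field = c("constant", "gradient", "two_region"),
                                   value = 1, axis = 3, v1 = 0, v2 = 1,
                                   boundary = 0, feature = "scalar") {
  field <- match.arg(field)
  idx <- as.matrix(expand.grid(x = seq_len(grid$dim[1]) - 1L,
                               y = seq_len(grid$dim[2]) - 1L,
                               z = seq_len(grid$dim[3]) - 1L))
  centers <- voxel_center(grid, idx)
  vals <- switch(field,
                 constant = rep(value, nrow(idx)),
                 gradient = centers[, axis],
                 two_region = ifelse(centers[, axis] < boundary, v1, v2))
  scalar_volume(array(vals, grid$dim), grid, feature)
}

#' Write a feature table as CSV
#' @param table feature-table data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#' @param path CSV path.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize truth records to JSON
#' @param truth list of [truth_record()]s.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(lapply(truth, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
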