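# Covariate-adjusted restricted cubic spline (C-RCS) lifespan trajectory
# models: least-squares fit of value ~ RCS(age) + sex, analytic per-year
# differences, dense-grid extrema, subject-level bootstrap bands and
# extremum confidence intervals, and cohort-binned rate summaries.

#' Pipeline configuration
#'
#' @param B bootstrap replicates. 200 is the desk-scale default; the
#'   full-scale analysis uses 10000.
#' @param ci_level confidence level for bands and extremum intervals.
#' @param step extremum/curve grid step in years (bounds the extremum age
#'   discretization error at step/2).
#' @param fdr_q false discovery rate for association masks.
#' @param knots RCS knot ages.
#' @param window,boundaries harmonization window (years) and boundary ages.
#' @param seed integer seed for all randomness.
#' @return list of validated settings, class `pipeline_config`.
#' @export
pipeline_config <- function(B = 200, ci_level = 0.95, step = 0.1,
                            fdr_q = 0.05, knots = c(2, 4, 22, 35, 75, 90),
                            window = 5, boundaries = c(22, 36), seed = 1) {
  stopifnot(B >= 1, ci_level > 0, ci_level < 1, step > 0,
            fdr_q > 0, fdr_q < 1, window > 0)
  structure(list(B = as.integer(B), ci_level = ci_level, step = step,
                 fdr_q = fdr_q, knots = as.numeric(knots), window = window,
                 boundaries = as.numeric(boundaries), seed = as.integer(seed)),
            class = "pipeline_config")
}

build_design <- function(data, spec, covariates) {
  X <- cbind(`(Intercept)` = 1, rcs_basis(data$age, spec))
  if ("sex" %in% covariates) {
    if (is.null(data$sex)) stop("covariate 'sex' requested but absent from data")
    X <- cbind(X, sexF = as.numeric(data$sex == "F"))
  }
  extra <- setdiff(covariates, "sex")
  if (length(extra)) stop("unsupported covariates: ", paste(extra, collapse = ", "))
  X
}

#' Fit a C-RCS trajectory model for one bundle x feature
#'
#' Ordinary least squares of `value ~ rcs_basis(age) + covariates`.
#'
#' @param data data.frame with columns `age`, `value`, and (if used as
#'   covariate / for bootstrap) `sex` and `subject_id`.
#' @param spec an [rcs_spec()].
#' @param covariates character vector; `"sex"` (additive shift for female)
#'   is the supported set, `character(0)` for none.
#' @return object of class `trajectory_model`: coefficients, basis spec,
#'   residual sd, n, fitted age range and observed female proportion.
#' @export
fit_trajectory <- function(data, spec = rcs_spec(), covariates = "sex") {
  if (is.null(data$age) || is.null(data$value))
    stop("data must have 'age' and 'value' columns")
  keep <- is.finite(data$age) & is.finite(data$value)
  data <- data[keep, , drop = FALSE]
  X <- build_design(data, spec, covariates)
  if (nrow(X) <= ncol(X))
    stop("need more observations (", nrow(X), ") than coefficients (", ncol(X), ")")
  if (sum(spec$knots >= min(data$age) & spec$knots <= max(data$age)) < 2)
    stop("observed ages must span at least 2 knots")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ", paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qrX, data$value)
  resid <- data$value - drop(X %*% coef)
  structure(list(coefficients = coef, spec = spec, covariates = covariates,
                 residual_sd = sqrt(sum(resid^2) / (nrow(X) - ncol(X))),
                 n = nrow(X), age_range = range(data$age),
                 p_female = if ("sex" %in% covariates) mean(data$sex == "F") else NA_real_),
            class = "trajectory_model")
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf("<trajectory_model> n = %d, ages %.2f-%.2f y, residual sd %.4g\n",
              x$n, x$age_range[1], x$age_range[2], x$residual_sd))
  print(x$coefficients)
  invisible(x)
}

sex_column_value <- function(model, sex_ref) {
  switch(sex_ref,
         average = model$p_female,
         male = 0,
         female = 1,
         stop("sex_ref must be 'average', 'male' or 'female'"))
}

#' Evaluate a fitted trajectory curve
#'
#' The sex covariate is held at the reference: `"average"` (observed female
#' proportion, so the curve is the cohort mean), `"male"` or `"female"`.
#'
#' @param model a [fit_trajectory()] model.
#' @param ages ages in years (within 0-120).
#' @param sex_ref covariate reference level.
#' @return fitted values.
#' @export
predict_curve <- function(model, ages, sex_ref = "average") {
  if (any(ages < 0 | ages > 120)) stop("ages must lie within [0, 120] years")
  X <- cbind(1, rcs_basis(ages, model$spec))
  if ("sex" %in% model$covariates)
    X <- cbind(X, sex_column_value(model, sex_ref))
  drop(X %*% model$coefficients)
}

#' Difference per year (analytic derivative of the fitted curve)
#'
#' @param model a [fit_trajectory()] model.
#' @param ages ages in years.
#' @return derivative in feature units per year.
#' @export
difference_per_year <- function(model, ages) {
  D <- rcs_basis_deriv(ages, model$spec)
  k1 <- ncol(D)
  drop(D %*% model$coefficients[2:(k1 + 1)])
}

#' Percent difference per year
#'
#' `100 * difference_per_year / fitted value`; ages where the fitted value
#' is zero give NaN, with a warning reporting the count.
#'
#' @param model a [fit_trajectory()] model.
#' @param ages ages in years.
#' @param sex_ref covariate reference, as in [predict_curve()].
#' @return percent change per year.
#' @export
percent_difference_per_year <- function(model, ages, sex_ref = "average") {
  f <- predict_curve(model, ages, sex_ref)
  d <- difference_per_year(model, ages)
  zero <- f == 0
  if (any(zero)) {
    warning(sum(zero), " age(s) with zero fitted value: percent difference undefined")
    f[zero] <- NA_real_
  }
  100 * d / f
}

extremum_from_values <- function(ages, values) {
  n <- length(ages)
  imax <- which.max(values)
  imin <- which.min(values)
  interior <- function(i) i > 1L && i < n
  if (interior(imax)) {
    list(type = "peak", age = ages[imax], value = values[imax])
  } else if (interior(imin)) {
    list(type = "minimum", age = ages[imin], value = values[imin])
  } else {
    list(type = "none", age = NA_real_, value = NA_real_)
  }
}

#' Locate the extremum of a fitted trajectory
#'
#' Dense-grid scan of the fitted curve. Returns a peak if the global
#' maximum is interior to the range, a minimum if the global minimum is
#' interior and no interior maximum exists, and type `"none"` for curves
#' that are monotone over the range (extremes only at the boundaries).
#'
#' @param model a [fit_trajectory()] model.
#' @param range age range to scan; defaults to the fitted range.
#' @param step grid step in years.
#' @param sex_ref covariate reference.
#' @return list with `type` (`"peak"`, `"minimum"` or `"none"`), `age` and
#'   `value`.
#' @export
find_extremum <- function(model, range = model$age_range, step = 0.1,
                          sex_ref = "average") {
  if (length(range) != 2 || range[1] >= range[2]) stop("invalid age range")
  grid <- seq(range[1], range[2], by = step)
  if (grid[length(grid)] < range[2]) grid <- c(grid, range[2])
  extremum_from_values(grid, predict_curve(model, grid, sex_ref))
}

#' Subject-level bootstrap of a trajectory fit
#'
#' Resamples subjects with replacement (all sessions of a drawn subject
#' enter the replicate, preserving the longitudinal structure of the
#' infant cohort), refits the C-RCS model, and collects curves and
#' extremum ages. Bands are per-age percentiles at `ci_level`; the
#' extremum interval is the percentile interval of extremum ages over
#' replicates that found the same extremum type as the point fit.
#' Rank-deficient replicates are dropped and counted; more than 10%
#' dropped is an error.
#'
#' @param data data.frame with `age`, `value`, `sex`, `subject_id`.
#' @param spec an [rcs_spec()].
#' @param covariates covariate set, as in [fit_trajectory()].
#' @param config a [pipeline_config()] (uses `B`, `ci_level`, `step`, `seed`).
#' @param age_grid evaluation grid; defaults to the fitted range at `step`.
#' @return object of class `trajectory_bootstrap`: `age_grid`, `fit`,
#'   `lower`, `upper`, `extremum` (point estimate with `ci_low`/`ci_high`
#'   and `n_same_type`), `B_used`, `B_dropped`.
#' @export
bootstrap_trajectory <- function(data, spec = rcs_spec(), covariates = "sex",
                                 config = pipeline_config(), age_grid = NULL) {
  model <- fit_trajectory(data, spec, covariates)
  if (is.null(data$subject_id)) stop("data must carry 'subject_id' for resampling")
  keep <- is.finite(data$age) & is.finite(data$value)
  data <- data[keep, , drop = FALSE]
  if (is.null(age_grid))
    age_grid <- seq(model$age_range[1], model$age_range[2], by = config$step)
  X <- build_design(data, spec, covariates)
  y <- data$value
  p <- ncol(X)
  Xg <- cbind(1, rcs_basis(age_grid, spec))
  sex_col <- if ("sex" %in% covariates) model$p_female else NULL

  subj_rows <- split(seq_len(nrow(data)), data$subject_id)
  n_subj <- length(subj_rows)
  set.seed(config$seed)
  curves <- matrix(NA_real_, length(age_grid), config$B)
  ext_type <- character(config$B)
  ext_age <- rep(NA_real_, config$B)
  dropped <- 0L
  for (b in seq_len(config$B)) {
    idx <- unlist(subj_rows[sample.int(n_subj, n_subj, replace = TRUE)],
                  use.names = FALSE)
    fit_b <- stats::lm.fit(X[idx, , drop = FALSE], y[idx])
    if (fit_b$rank < p) { dropped <- dropped + 1L; next }
    coef_b <- fit_b$coefficients
    curve_b <- drop(Xg %*% coef_b[seq_len(ncol(Xg))])
    if (!is.null(sex_col)) curve_b <- curve_b + coef_b[p] * sex_col
    curves[, b] <- curve_b
    ext <- extremum_from_values(age_grid, curve_b)
    ext_type[b] <- ext$type
    ext_age[b] <- ext$age
  }
  if (dropped > 0.1 * config$B)
    stop(dropped, " of ", config$B, " bootstrap replicates were rank deficient")
  used <- which(!is.na(curves[1, ]))
  alpha <- (1 - config$ci_level) / 2
  bands <- apply(curves[, used, drop = FALSE], 1, stats::quantile,
                 probs = c(alpha, 1 - alpha), names = FALSE)
  point_ext <- extremum_from_values(age_grid,
                                    predict_curve(model, age_grid, "average"))
  same <- used[ext_type[used] == point_ext$type & point_ext$type != "none"]
  ext_ci <- if (length(same)) {
    stats::quantile(ext_age[same], c(alpha, 1 - alpha), names = FALSE)
  } else c(NA_real_, NA_real_)
  structure(list(age_grid = age_grid,
                 fit = predict_curve(model, age_grid, "average"),
                 lower = bands[1, ], upper = bands[2, ],
                 extremum = c(point_ext,
                              list(ci_low = ext_ci[1], ci_high = ext_ci[2],
                                   n_same_type = length(same))),
                 model = model, B_used = length(used), B_dropped = dropped,
                 seed = config$seed),
            class = "trajectory_bootstrap")
}

#' @export
print.trajectory_bootstrap <- function(x, ...) {
  cat(sprintf("<trajectory_bootstrap> B = %d used (%d dropped); extremum: %s",
              x$B_used, x$B_dropped, x$extremum$type))
  if (x$extremum$type != "none")
    cat(sprintf(" at %.2f y [%.2f, %.2f]", x$extremum$age,
                x$extremum$ci_low, x$extremum$ci_high))
  cat("\n")
  invisible(x)
}

#' Default lifespan age bins
#'
#' Cohort-aligned bins: infant 0-5, development 5-21, young adult 22-35,
#' aging 36+ years. Each bin is extended half-open to the next bin's lower
#' edge so the bins tile the age axis without overlap.
#'
#' @return data.frame with `bin`, `low`, `high`.
#' @export
default_bins <- function() {
  data.frame(bin = c("infant", "development", "young_adult", "aging"),
             low = c(0, 5, 22, 36), high = c(5, 22, 36, Inf),
             stringsAsFactors = FALSE)
}

#' Cohort-binned mean percent difference per year
#'
#' Averages the per-age percent difference per year over the grid points
#' falling in each bin (`low <= age < high`). Empty bins give NaN with a
#' warning.
#'
#' @param age_grid ages of the curve grid.
#' @param pct_per_year percent difference per year at those ages.
#' @param bins bin table as in [default_bins()].
#' @return data.frame with `bin` and `mean_pct_per_year`.
#' @export
bin_rates <- function(age_grid, pct_per_year, bins = default_bins()) {
  stopifnot(length(age_grid) == length(pct_per_year))
  out <- vapply(seq_len(nrow(bins)), function(i) {
    sel <- age_grid >= bins$low[i] & age_grid < bins$high[i]
    if (!any(sel)) return(NaN)
    mean(pct_per_year[sel], na.rm = TRUE)
  }, numeric(1))
  if (any(is.nan(out)))
    warning("empty bins: ", paste(bins$bin[is.nan(out)], collapse = ", "))
  data.frame(bin = bins$bin, mean_pct_per_year = out, stringsAsFactors = FALSE)
}
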