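# Continuity-based cohort harmonization. The cohorts partition the age
# axis with no covariate overlap, so batch-correction methods that model a
# site effect alongside shared covariates cannot be used. Instead, the
# acquisition offset of one target cohort (here the young-adult cohort) is
# estimated from the discontinuity of the feature-vs-age relationship at
# each cohort boundary: local linear fits on either side of the boundary
# are extrapolated to the boundary age, and the offset is the mean
# target-minus-neighbour discrepancy over all boundaries.

#' Estimate per-feature additive cohort offsets
#'
#' For every bundle x feature, fits `value ~ age` to target-cohort rows
#' within `window` years of each boundary (on the target's side) and to
#' non-target rows on the opposite side, and takes
#' `discrepancy(b) = target prediction at b - neighbour prediction at b`.
#' The offset is the mean discrepancy over boundaries.
#'
#' @param table feature table (long in bundle, wide in features).
#' @param target_cohort cohort whose rows carry the offset.
#' @param boundaries boundary ages in years (defaults 22 and 36, the
#'   young-adult cohort's joins with its neighbours).
#' @param window years used on each side of a boundary.
#' @param features feature columns to estimate; default: all numeric
#'   columns after the metadata columns.
#' @param min_n minimum rows required in each window.
#' @return object of class `offset_estimates`: list with `offsets`
#'   (data.frame bundle, feature, target_cohort, offset) and `details`
#'   (per-boundary discrepancies and window row counts).
#' @export
estimate_offset <- function(table, target_cohort = "young_adult",
                            boundaries = c(22, 36), window = 5,
                            features = NULL, min_n = 10) {
  stopifnot(window > 0, length(boundaries) >= 1)
  if (!target_cohort %in% table$cohort)
    stop("target cohort '", target_cohort, "' not present in the table")
  if (is.null(features)) features <- feature_columns(table)
  if (!length(features)) stop("no feature columns found")
  bundles <- unique(table$bundle)
  target_mid <- stats::median(table$age[table$cohort == target_cohort])

  offsets <- list(); details <- list()
  for (bd in bundles) {
    tb <- table[table$bundle == bd, , drop = FALSE]
    for (f in features) {
      disc <- numeric(0)
      for (b in boundaries) {
        target_above <- target_mid >= b
        t_rows <- tb$cohort == target_cohort &
          (if (target_above) tb$age >= b & tb$age <= b + window
           else tb$age >= b - window & tb$age <= b)
        n_rows <- tb$cohort != target_cohort &
          (if (target_above) tb$age >= b - window & tb$age <= b
           else tb$age >= b & tb$age <= b + window)
        if (sum(t_rows) < min_n || sum(n_rows) < min_n)
          stop(sprintf(
            "insufficient rows near boundary %g y (window %g y) for %s/%s: target %d, neighbour %d",
            b, window, bd, f, sum(t_rows), sum(n_rows)))
        fit_t <- stats::lm(stats::reformulate("age", f), data = tb[t_rows, ])
        fit_n <- stats::lm(stats::reformulate("age", f), data = tb[n_rows, ])
        at_b <- data.frame(age = b)
        d <- unname(stats::predict(fit_t, at_b) - stats::predict(fit_n, at_b))
        disc <- c(disc, d)
        details[[length(details) + 1L]] <- data.frame(
          bundle = bd, feature = f, boundary = b, discrepancy = d,
          n_target = sum(t_rows), n_neighbour = sum(n_rows), window = window,
          stringsAsFactors = FALSE)
      }
      offsets[[length(offsets) + 1L]] <- data.frame(
        bundle = bd, feature = f, target_cohort = target_cohort,
        offset = mean(disc), stringsAsFactors = FALSE)
    }
  }
  structure(list(offsets = do.call(rbind, offsets),
                 details = do.call(rbind, details),
                 target_cohort = target_cohort, boundaries = boundaries,
                 window = window),
            class = "offset_estimates")
}

#' @export
print.offset_estimates <- function(x, ...) {
  cat(sprintf("<offset_estimates> target '%s', boundaries %s, window %g y\n",
              x$target_cohort, paste(x$boundaries, collapse = "/"), x$window))
  print(x$offsets)
  invisible(x)
}

#' Subtract estimated offsets from the target cohort
#'
#' Target-cohort rows have each feature shifted by `-offset`; all other
#' rows are returned unchanged. Every bundle x feature present in the
#' table (over the estimated features) must have an estimate.
#'
#' @param table feature table.
#' @param estimates an [estimate_offset()] result.
#' @return harmonized feature table.
#' @export
apply_offset <- function(table, estimates) {
  stopifnot(inherits(estimates, "offset_estimates"))
  est <- estimates$offsets
  target <- table$cohort == estimates$target_cohort
  for (bd in unique(table$bundle)) {
    for (f in feature_columns(table)) {
      row <- est[est$bundle == bd & est$feature == f, ]
      if (nrow(row) == 0)
        stop("no offset estimate for bundle '", bd, "', feature '", f, "'")
      sel <- target & table$bundle == bd
      table[[f]][sel] <- table[[f]][sel] - row$offset
    }
  }
  table
}

# metadata columns of the canonical feature-table schema
feature_columns <- function(table) {
  meta <- c("subject_id", "session_id", "age", "sex", "cohort", "bundle")
  setdiff(names(table)[vapply(table, is.numeric, logical(1))], meta)
}
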