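# End-to-end synthetic pipeline: generate -> harmonize -> fit C-RCS with
# bootstrap -> bin rates -> association and coupling analyses, with a run
# manifest (config snapshot, per-file md5, row counts, stage timings).
# Reruns with the same config and seed reproduce identical numeric output.

#' Default synthetic truth set for the demonstration pipeline
#'
#' Three bundles x two features with distinct lifespan shapes: an
#' FA-like rise-then-decline (poisson-like curve peaking in the fourth
#' decade) and a volume-like inverted-U (quadratic). Both carry a
#' young-adult acquisition offset, a small sex effect, and residual noise
#' around 5% of each feature's dynamic range.
#'
#' @param bundles bundle names.
#' @return list of [truth_record()]s.
#' @export
default_truth <- function(bundles = c("AF_left", "CST_left", "CC_genu")) {
  out <- list()
  for (i in seq_along(bundles)) {
    # stagger curve parameters across bundles so rates differ by pathway
    g <- 0.9 + 0.1 * i
    out[[length(out) + 1L]] <- truth_record(
      bundles[i], "FA", "poisson_like",
      params = c(0.30, 0.012 * g, 1 / (25 + 5 * i)),
      ya_offset = 0.03, noise_sd = 0.012, sex_effect = -0.005)
    out[[length(out) + 1L]] <- truth_record(
      bundles[i], "volume", "quadratic",
      params = c(8000 * g, 160 * g, -2.2 * g),
      ya_offset = 400, noise_sd = 350, sex_effect = -250)
  }
  out
}

#' Per-cohort table summary
#'
#' Subject, session counts and age ranges per cohort, plus pooled totals.
#' Sessions are unique subject x session pairs (the table is long in
#' bundle, so each session contributes one row per bundle).
#'
#' @param table feature table (possibly empty).
#' @return data.frame with one row per cohort and a final `pooled` row.
#' @export
summarize_table <- function(table) {
  if (is.null(table) || nrow(table) == 0) {
    return(data.frame(cohort = "pooled", n_subjects = 0L, n_sessions = 0L,
                      age_min = NA_real_, age_max = NA_real_,
                      stringsAsFactors = FALSE))
  }
  key <- paste(table$subject_id, table$session_id)
  one <- function(rows, label) {
    data.frame(cohort = label,
               n_subjects = length(unique(table$subject_id[rows])),
               n_sessions = length(unique(key[rows])),
               age_min = min(table$age[rows]), age_max = max(table$age[rows]),
               stringsAsFactors = FALSE)
  }
  cohorts <- unique(table$cohort)
  out <- do.call(rbind, lapply(cohorts, function(co)
    one(table$cohort == co, co)))
  rbind(out, one(rep(TRUE, nrow(table)), "pooled"))
}

#' Run the full synthetic pipeline
#'
#' Generates a cohort table from `truth`, estimates and removes the
#' young-adult offset, fits a bootstrapped C-RCS trajectory per bundle x
#' feature, bins percent differences per year into lifespan cohorts,
#' computes cross-feature correlations per bundle (raw and partial),
#' rate coupling per bin, and development-vs-aging coupling per feature.
#' All tables are written as CSV under `out_dir` together with a JSON run
#' manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param truth list of [truth_record()]s.
#' @param cohorts list of [cohort_spec()]s.
#' @return list with the in-memory results (`table`, `harmonized`,
#'   `offsets`, `curves`, `rates`, `correlations`, `coupling`,
#'   `dev_aging`, `summary`, `manifest`), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         truth = default_truth(),
                         cohorts = default_cohorts(n_per_cohort = 250)) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config), stages = list(), files = list())
  t_all <- Sys.time()
  spec <- rcs_spec(config$knots)
  features <- unique(vapply(truth, function(tr) tr$feature, character(1)))
  bundles <- unique(vapply(truth, function(tr) tr$bundle_id, character(1)))

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  emit <- function(df, file, stage_name) {
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    manifest$files[[file]] <<- list(stage = stage_name,
                                    md5 = unname(tools::md5sum(path)),
                                    rows = nrow(df))
    path
  }

  gen <- stage("simulate", generate_feature_table(truth, cohorts, config$seed))
  tab <- gen$table
  emit(tab, "feature_table.csv", "simulate")
  write_truth_json(truth, file.path(out_dir, "truth.json"))
  manifest$files[["truth.json"]] <- list(
    stage = "simulate", md5 = unname(tools::md5sum(file.path(out_dir, "truth.json"))),
    rows = length(truth))

  summary_df <- summarize_table(tab)
  emit(summary_df, "cohort_summary.csv", "summarize")

  offsets <- stage("harmonize", estimate_offset(
    tab, boundaries = config$boundaries, window = config$window, min_n = 5))
  harm <- apply_offset(tab, offsets)
  emit(offsets$offsets, "offsets.csv", "harmonize")
  emit(harm, "harmonized.csv", "harmonize")

  bins <- default_bins()
  curves <- list(); rate_rows <- list()
  stage("fit", {
    for (bd in bundles) {
      for (f in features) {
        rows <- harm[harm$bundle == bd, ]
        dat <- data.frame(age = rows$age, value = rows[[f]], sex = rows$sex,
                          subject_id = rows$subject_id)
        boot <- bootstrap_trajectory(dat, spec, "sex", config)
        model <- boot$model
        pct <- percent_difference_per_year(model, boot$age_grid)
        curves[[paste(bd, f, sep = ".")]] <- list(
          bundle = bd, feature = f, boot = boot, pct_per_year = pct)
        br <- bin_rates(boot$age_grid, pct, bins)
        rate_rows[[length(rate_rows) + 1L]] <- data.frame(
          bundle = bd, feature = f, br, stringsAsFactors = FALSE)
      }
    }
    NULL
  })
  rates <- do.call(rbind, rate_rows)
  emit(rates, "cohort_rates.csv", "fit")
  curve_df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(bundle = cv$bundle, feature = cv$feature,
               age = cv$boot$age_grid, fit = cv$boot$fit,
               lower = cv$boot$lower, upper = cv$boot$upper,
               pct_per_year = cv$pct_per_year, stringsAsFactors = FALSE)))
  emit(curve_df, "curves.csv", "fit")
  ext_df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(bundle = cv$bundle, feature = cv$feature,
               type = cv$boot$extremum$type, age = cv$boot$extremum$age,
               ci_low = cv$boot$extremum$ci_low,
               ci_high = cv$boot$extremum$ci_high, stringsAsFactors = FALSE)))
  emit(ext_df, "extrema.csv", "fit")

  correlations <- stage("associate", {
    out <- list()
    for (bd in bundles) {
      rows <- harm[harm$bundle == bd, ]
      for (m in c("pearson", "partial")) {
        at <- association_table(feature_correlations(
          rows, features, method = m, fdr_q = config$fdr_q))
        at <- data.frame(bundle = bd, method = m, at, stringsAsFactors = FALSE)
        out[[paste(bd, m)]] <- at
      }
    }
    do.call(rbind, out)
  })
  emit(correlations, "feature_correlations.csv", "associate")

  coupling <- stage("couple_rates", {
    out <- list()
    for (bn in bins$bin) {
      sub <- rates[rates$bin == bn, ]
      mat <- matrix(NA_real_, length(bundles), length(features),
                    dimnames = list(bundles, features))
      for (i in seq_len(nrow(sub)))
        mat[sub$bundle[i], sub$feature[i]] <- sub$mean_pct_per_year[i]
      if (length(features) >= 2 && sum(stats::complete.cases(mat)) >= 3) {
        at <- association_table(rate_coupling(mat, config$fdr_q))
        out[[bn]] <- data.frame(bin = bn, at, stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  if (!is.null(coupling)) emit(coupling, "rate_coupling.csv", "couple_rates")

  dev_aging <- do.call(rbind, lapply(features, function(f) {
    rd <- rates[rates$feature == f & rates$bin == "development", ]
    ra <- rates[rates$feature == f & rates$bin == "aging", ]
    m <- merge(rd[, c("bundle", "mean_pct_per_year")],
               ra[, c("bundle", "mean_pct_per_year")], by = "bundle")
    if (nrow(m) < 3) return(NULL)
    da <- dev_aging_coupling(m$mean_pct_per_year.x, m$mean_pct_per_year.y)
    data.frame(feature = f, r = da$r, p = da$p, n_pathways = da$n_pathways,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(dev_aging)) emit(dev_aging, "dev_aging_coupling.csv", "couple_rates")

  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  manifest$n_bundles <- length(bundles)
  manifest$n_features <- length(features)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(table = tab, harmonized = harm, offsets = offsets,
                 curves = curves, rates = rates, correlations = correlations,
                 coupling = coupling, dev_aging = dev_aging,
                 summary = summary_df, manifest = manifest))
}
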