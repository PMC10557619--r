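#!/usr/bin/env Rscript
# Stage 5: C-RCS lifespan trajectories with subject-level bootstrap.
#
# Fits value ~ RCS(age; knots 2, 4, 22, 35, 75, 90) + sex per bundle x
# feature on the harmonized table, derives the analytic difference per
# year and percent difference per year, locates peaks with bootstrap 95%
# intervals (resampling subjects, so infant sessions travel together),
# and bins percent differences into the four lifespan cohorts.

suppressPackageStartupMessages(library(bundlespan))

out <- "results/trajectories"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

harm <- read_feature_table("results/harmonized/harmonized.csv")
cfg <- pipeline_config(B = 200, seed = 1)
spec <- rcs_spec(cfg$knots)

bundles <- unique(harm$bundle)
features <- c("FA", "volume")
curve_rows <- rate_rows <- ext_rows <- list()
for (bd in bundles) {
  rows <- harm[harm$bundle == bd, ]
  for (f in features) {
    dat <- data.frame(age = rows$age, value = rows[[f]], sex = rows$sex,
                      subject_id = rows$subject_id)
    bt <- bootstrap_trajectory(dat, spec, "sex", cfg)
    pct <- percent_difference_per_year(bt$model, bt$age_grid)
    curve_rows[[paste(bd, f)]] <- data.frame(
      bundle = bd, feature = f, age = bt$age_grid, fit = bt$fit,
      lower = bt$lower, upper = bt$upper, pct_per_year = pct)
    ext_rows[[paste(bd, f)]] <- data.frame(
      bundle = bd, feature = f, type = bt$extremum$type,
      peak_age = bt$extremum$age, ci_low = bt$extremum$ci_low,
      ci_high = bt$extremum$ci_high)
    rate_rows[[paste(bd, f)]] <- data.frame(
      bundle = bd, feature = f, bin_rates(bt$age_grid, pct))
  }
}
curves <- do.call(rbind, curve_rows)
extrema <- do.call(rbind, ext_rows)
rates <- do.call(rbind, rate_rows)
write.csv(curves, file.path(out, "curves.csv"), row.names = FALSE)
write.csv(extrema, file.path(out, "extrema.csv"), row.names = FALSE)
write.csv(rates, file.path(out, "cohort_rates.csv"), row.names = FALSE)

cat("Bootstrap extrema (volume truth peaks at ~36 y, FA-like curves in the 30s):\n")
print(extrema, digits = 4, row.names = FALSE)
cat("\nCohort-binned mean percent difference per year:\n")
print(reshape(rates, idvar = c("bundle", "feature"), timevar = "bin",
              direction = "wide"), digits = 3, row.names = FALSE)
cat("\nExpected pattern: strongly positive infant rates, smaller development\n")
cat("rates, near-zero young-adult rates, negative aging rates.\n")
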