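#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates a four-cohort lifespan study: a session x bundle feature table
# with known ground-truth trajectories, a young-adult acquisition offset,
# sex effects and noise; three parametric streamline bundles with known
# geometry (written as TRK and TCK); and analytic scalar volumes for the
# sampling stage. Everything downstream reads only these files.

suppressPackageStartupMessages(library(bundlespan))

seed <- 1
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- default_truth()
cohorts <- default_cohorts(n_per_cohort = 250, infant_sessions = c(1, 3))
gen <- generate_feature_table(truth, cohorts, seed = seed)
write_feature_table(gen$table, file.path(out, "feature_table.csv"))
write_truth_json(truth, file.path(out, "truth.json"))

summ <- summarize_table(gen$table)
write.csv(summ, file.path(out, "cohort_summary.csv"), row.names = FALSE)
cat("Cohort design (sessions are longitudinal for infants only):\n")
print(summ)

# parametric bundle fixtures with analytically known shape
fixtures <- list(
  straight_tube = generate_bundle("straight_tube", n_streamlines = 500,
                                  length = 100, radius = 5, seed = seed),
  arc = generate_bundle("arc", n_streamlines = 500, radius = 50,
                        angle = pi, tube_radius = 3, seed = seed + 1),
  fan = generate_bundle("fan", n_streamlines = 200, length = 80,
                        spread = 25, seed = seed + 2))
for (nm in names(fixtures)) {
  write_trk(fixtures[[nm]], file.path(out, paste0(nm, ".trk")))
  write_tck(fixtures[[nm]], file.path(out, paste0(nm, ".tck")))
}
cat("\nWrote", length(fixtures), "bundle fixtures (TRK + TCK) to", out, "\n")

# scalar volumes on the tube's grid: a constant FA-like map and a
# two-region thickness-like map split at the tube midpoint
g <- fixtures$straight_tube$grid
write_volume_nifti(generate_scalar_volume(g, "constant", value = 0.42,
                                          feature = "FA"),
                   file.path(out, "fa_constant.nii.gz"))
write_volume_nifti(generate_scalar_volume(g, "two_region", axis = 3, v1 = 2,
                                          v2 = 4, boundary = 50,
                                          feature = "thickness"),
                   file.path(out, "thickness_two_region.nii.gz"))
cat("Wrote scalar volumes (NIfTI) for the sampling stage\n")
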