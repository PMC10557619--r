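#!/usr/bin/env Rscript
# Stage 4: continuity-based harmonization of the young-adult cohort.
#
# The young-adult cohort carries a known injected acquisition offset
# (+0.03 FA, +400 mm^3 volume in the default truth). Local linear fits on
# both sides of the 22 y and 36 y cohort boundaries estimate the offset
# per bundle x feature; the harmonized table has it subtracted.

suppressPackageStartupMessages(library(bundlespan))

src <- "results/synthetic"
out <- "results/harmonized"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tab <- read_feature_table(file.path(src, "feature_table.csv"))
est <- estimate_offset(tab, target_cohort = "young_adult",
                       boundaries = c(22, 36), window = 5, min_n = 5)
harm <- apply_offset(tab, est)

write.csv(est$offsets, file.path(out, "offsets.csv"), row.names = FALSE)
write.csv(est$details, file.path(out, "offset_details.csv"), row.names = FALSE)
write_feature_table(harm, file.path(out, "harmonized.csv"))

cat("Estimated young-adult offsets (injected truth: FA +0.03, volume +400):\n")
print(est$offsets, digits = 4)
cat("\nPer-boundary discrepancies and window row counts:\n")
print(est$details, digits = 4)

re <- estimate_offset(harm, min_n = 5)
cat(sprintf("\nRe-estimated offsets after harmonization (max |offset|: %.4g FA, %.4g mm^3)\n",
            max(abs(re$offsets$offset[re$offsets$feature == "FA"])),
            max(abs(re$offsets$offset[re$offsets$feature == "volume"]))))
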