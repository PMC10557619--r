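#!/usr/bin/env Rscript
# Stage 2: macrostructural shape features of the bundle fixtures.
#
# Reads the TRK tractograms written by stage 1, computes the ten shape
# features, and checks them against the analytic geometry of each fixture:
# a straight tube has curl 1 and a cylinder volume, a semicircular arc has
# curl pi/2, and the fan's endpoint spread shows up in its tail surface.

suppressPackageStartupMessages(library(bundlespan))

src <- "results/synthetic"
out <- "results/shape"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

features <- do.call(rbind, lapply(c("straight_tube", "arc", "fan"),
                                  function(nm) {
  bundle <- read_trk(file.path(src, paste0(nm, ".trk")))
  compute_shape_features(bundle)
}))
write.csv(features, file.path(out, "shape_features.csv"), row.names = FALSE)

cat("Shape features of the parametric fixtures:\n")
print(features, digits = 4)

tube <- features[features$bundle == "straight_tube", ]
arc <- features[features$bundle == "arc", ]
cat(sprintf("\nStraight tube: curl %.4f (analytic 1), length %.2f mm (100)\n",
            tube$curl, tube$length))
cat(sprintf("Semicircular arc: curl %.4f (analytic pi/2 = %.4f)\n",
            arc$curl, pi / 2))
cat(sprintf("Tube volume %.0f mm^3 vs analytic cylinder %.0f mm^3 (%.1f%% off;\n",
            tube$volume, pi * 25 * 100,
            100 * abs(tube$volume / (pi * 25 * 100) - 1)))
cat("  vertex-based occupancy under-fills at 500 streamlines; the tests use\n")
cat("  2000 streamlines on a 0.5 mm grid where the error drops below 10%)\n")
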