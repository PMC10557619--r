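Package: bundlespan
Title: Lifespan Trajectory Analysis of White Matter Bundle Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of white matter bundle features across
    the human lifespan: macrostructural shape features of streamline
    bundles (volume, length, span, curl, diameter, elongation, surface
    areas), tract-averaged microstructure and streamline-endpoint cortical
    sampling from scalar volumes, continuity-based harmonization of an
    age-partitioned multi-cohort table, covariate-adjusted restricted
    cubic spline (C-RCS) trajectory modeling with subject-level bootstrap
    confidence bands and peak-age intervals, and cross-feature and
    cross-rate association analyses with false discovery rate control.
    Includes a synthetic-data generator with known ground truth so the
    whole pipeline is testable end to end, plus TRK/TCK tractogram and
    NIfTI volume I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    splines,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
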