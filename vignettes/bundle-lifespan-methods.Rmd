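---
title: "Methods: lifespan trajectories of white matter bundle features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifespan trajectories of white matter bundle features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bundlespan)
```

## The problem

Characterizing how white matter pathways mature and degrade requires
following three families of features over the whole lifespan: voxel-wise
*microstructure* (FA, MD, AD, RD, ICVF, ISOVF, OD) averaged over a tract,
*macrostructure* (ten shape features of the streamline bundle), and
*cortical* features probed where the bundle's streamlines terminate.
Lifespan data come as several age-partitioned cohorts (infant,
development, young adult, aging) acquired with different protocols, so the
analysis must harmonize cohorts that share no age overlap before fitting
smooth age trajectories and comparing rates of change across features and
pathways.

This package implements that pipeline end to end and ships a
synthetic-data generator with known ground truth, so every stage is
testable without access to restricted cohort data.

## Shape features of a bundle

A bundle is an ordered set of 3D polylines in world mm (RAS+). The ten
features and their conventions:

* **length**: mean per-streamline arc length (mm);
* **span**: mean per-streamline straight-line end-to-end distance (mm);
* **curl** = length / span, 1 for straight bundles, growing with
  curvature; a closed loop (span ~ 0) yields `NA` rather than infinity;
* **volume**: occupied-voxel count x voxel volume, where a voxel is
  occupied iff a streamline vertex falls in it after densifying segments
  below half a voxel;
* **volume of endpoints**: same, using only first/last vertices;
* **diameter**: of the cylinder with the bundle's volume and length,
  `2 sqrt(V / (pi L))`; **elongation** = length / diameter;
* **surface area**: exposed voxel faces of the occupancy mask under
  6-connectivity, times face area; **head/tail surface areas** apply the
  same rule to the endpoint masks of the two end clusters. The *head* is
  the end whose centroid sits lower on the dominant displacement axis
  (most left / posterior / inferior; ties broken x, then y, then z).

Two dialect choices are deliberate. Occupancy is by densified-vertex
membership, not exact segment-voxel intersection: at half-voxel spacing
the difference is below the voxelization error itself, and the rule is
cheap and deterministic. Surface area counts exposed voxel faces rather
than running marching cubes: it is exact on analytic fixtures (a unit
voxel has 6 mm^2; a 1x1x10 rod has 42 mm^2), which makes the geometry
testable, at the cost of overestimating smooth surfaces by a known
staircase factor. Whether span should be the per-streamline mean or the
distance between end-cluster centroids is genuinely open; the
per-streamline mean is used and documented here.

Voxel conventions: indices 0-based; a voxel covers the half-open box
`[edge, edge + size)`; world coordinates are mm in RAS+. Points sitting
numerically on a voxel edge are nudged by 1e-7 voxel so that integer-voxel
translations of a bundle cannot flip membership through floating-point
noise.

## Sampling scalar volumes

Tract averages are unweighted means over the occupied voxels ("averaged
across all voxels in the entire tract"), not weighted by streamline
visits. Endpoint probing reads the *containing voxel* of each
streamline's two termini (no interpolation, matching endpoint-map
practice), averages the two ends per streamline, then averages over
streamlines. Cortical maps are undefined off the ribbon, so NaN policy
matters: a one-sided NaN uses the finite end, both-NaN streamlines are
dropped and counted, and bundles with no cortical endpoint at all (e.g.
mid-brain pathways) propagate as missing values rather than zeros.

## Harmonization by continuity

The four cohorts partition the age axis, so batch correction methods that
need covariate overlap cannot be applied. Instead the young-adult cohort's
additive acquisition offset is estimated from the discontinuity of the
feature-age relationship at its two boundaries (22 y with development,
36 y with aging): a linear model `value ~ age` is fitted to each side's
rows within a window (default 5 y), both fits are evaluated at the
boundary age, and the offset is the mean target-minus-neighbour
discrepancy over boundaries. The harmonized table subtracts the offset
from target-cohort rows only.

The exact adjustment used with the real cohorts is described only in
supplementary material not available here, so this estimator is a declared
convention: the minimal one consistent with a continuity assumption. Its
error properties are quantified in tests rather than assumed: with a
locally linear truth the recovery is exact to numerical precision; with a
quadratic truth the extrapolation bias is bounded by the curvature times
window^2 / 8 (the two boundaries' biases largely cancel when curvature is
shared); estimator variance shrinks as cohort size grows. The window
trades bias (larger windows see more curvature) against variance (smaller
windows hold fewer sessions); 5 y keeps the quadratic-truth bias an order
of magnitude below the offsets of interest at realistic curvatures. The
offset is additive, not multiplicative, because the phenomenon being
removed is a level shift between acquisitions.

## C-RCS trajectories

Trajectories are fitted per bundle x feature by ordinary least squares of
`value ~ RCS(age) + sex`, where RCS is the restricted cubic spline
(natural cubic spline) basis in Harrell's truncated-power form with
`(t_k - t_1)^2` normalization and knots at **2, 4, 22, 35, 75, 90 years**
(expected developmental and aging shifts; 5-6 knots balance flexibility
against overfitting). With k knots the basis has one linear and k - 2
nonlinear columns; the fitted curve is linear beyond the boundary knots
and twice continuously differentiable everywhere — both properties are
tested numerically, and the fitted values are cross-checked against a
natural-spline fit from a different basis spanning the same space.

"Covariate-adjusted" means additive covariate terms; sex is the default
(and only built-in) covariate, matching the partial-correlation controls.
Curves are reported with sex held at the observed female proportion so
they represent the cohort mean; male/female reference levels are
available.

* **Difference per year** is the analytic derivative of the fitted spline
  (checked against central finite differences).
* **Percent difference per year** is `100 x derivative / fitted value`,
  NaN where the fitted value crosses zero (reported, not silently
  dropped).
* **Peaks/minima** come from a dense-grid scan (default 0.1 y, bounding
  the age error at 0.05 y) rather than root-finding on the derivative,
  which is robust to multiple local extrema; a curve whose global
  extremes sit on the range boundary is classified `none` (monotone) —
  mirroring pathways without a well-defined maximum.
* **Uncertainty**: nonparametric bootstrap resampling *subjects* with
  replacement — the infant cohort is longitudinal, so a subject's sessions
  travel together. Bands are per-age 2.5/97.5 percentiles; the peak-age
  interval is the percentile interval of the argmax over replicates that
  found the same extremum type. The full-scale analysis uses B = 10,000;
  the desk default is B = 200, which the tests show already achieves
  near-nominal coverage at the tested problem sizes. Rank-deficient
  replicates are dropped and counted (more than 10% dropped is an error).

Rates are summarized by binning the percent-difference-per-year curve
into the four lifespan groups (infant 0-5, development 5-21, young adult
22-35, aging 36+). As printed, those groups leave the slivers 21-22 and
35-36 unassigned; each bin here extends half-open to the next bin's lower
edge so the bins tile the age axis — the bin means move by less than the
grid step's worth of curve.

## Associations

Cross-feature structure uses Pearson correlation throughout ("partial
linear correlation" in partial mode: both features are residualized on
age and sex, with the t-test degrees of freedom reduced accordingly).
Rate coupling correlates two features' per-pathway rate vectors within a
cohort bin; development-vs-aging coupling correlates one feature's
development rates against its aging rates across pathways (the
gain-predicts-loss test). Anterior-posterior gradients fit linear and
quadratic models of rate against each pathway's MNI y centroid.

Multiple-comparison control is Benjamini-Hochberg at q = 0.05, applied
within each matrix (per pathway x cohort for session-level correlations,
per cohort for rate coupling); the family definition is not fixed by the
source analysis, so it is declared in the output metadata. Missing
entries (cortical features of mid-brain pathways) are deleted pairwise,
preserving power for complete pairs; pairs with fewer than 3 complete
pathways stay NA.

## The synthetic generator

The generator emulates the statistical structure the analysis relies on,
with Table-1-style cohorts: infant 0.03-6.1 y (optionally longitudinal,
1-5 sessions at 0.5-1.5 y increments, truncated at the cohort bound),
development 5.5-21.9, young adult 22-37, aging 36-100. Ages are uniform
within cohort bounds — the simplest density covering the fitting domain,
since only ranges are reported. Sex is Bernoulli(0.5) (no per-cohort sex
ratios are reported). Values follow a smooth truth curve (quadratic,
poisson-like `c0 + c1 a exp(-c2 a)`, or interpolated spline) plus an
additive sex effect, a young-adult-only offset, and Gaussian noise.
Recovery tests use noise at 5% of the truth curve's dynamic range.

Bundle fixtures (straight tube, circular arc, fan) have analytically
known geometry, and scalar-volume fixtures (constant, axis gradient,
two-region) have known values at every voxel centre, so shape features
and samplers are checked against closed forms, not regression baselines.

What the generator does *not* emulate: realistic diffusion signal or
anatomy, scanner physics, motion, spatially correlated noise,
heteroscedasticity across age, or site effects beyond a single additive
offset. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to every property of
real imaging data.

## Problem sizes and numerical choices

The test-suite simulations use desk-scale sizes chosen so the whole suite
runs in minutes: 100-500 subjects per cohort, 20-seed recovery loops,
100-replicate coverage studies at B = 200, and 2000-streamline fixtures
on 0.5 mm grids for voxelization accuracy. Full-scale settings (Table-1
subject counts, B = 10,000) are presets one configuration switch away.
Determinism is part of the contract: every stochastic routine takes a
seed, and the end-to-end pipeline writes byte-identical outputs when
rerun with the same configuration.

Known limitations: the offset estimator assumes near-linearity of the
truth within the boundary windows; percentile-of-argmax intervals inherit
the spline's approximation bias when the truth is outside the model class
(visible as a fraction-of-a-year bias for a strict quadratic truth);
voxel-face surface areas overestimate smooth surfaces; and the
per-streamline span convention differs from an end-centroid convention
for strongly fanning bundles.
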