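# bundlespan

Lifespan trajectory analysis of white matter bundle features.

Studies of brain development and aging describe how features of white
matter pathways — tract-averaged microstructure (FA, MD, AD, RD, ICVF,
ISOVF, OD), bundle macrostructure (volume, endpoint volume, length, span,
curl, diameter, elongation, and total/head/tail surface areas), and the
cortical features at streamline endpoints — change from birth to old age.
The data typically come from several age-partitioned cohorts with
different acquisitions, which poses three statistical problems this
package solves as a pipeline:

1. **Harmonization without covariate overlap.** The cohorts share no ages,
   so site-effect models cannot be fitted. A continuity-based estimator
   fits local linear models `value ~ age` on both sides of each cohort
   boundary (22 y and 36 y for the young-adult cohort, window 5 y) and
   removes the mean boundary discrepancy as an additive offset.
2. **Trajectory modeling.** Covariate-adjusted restricted cubic spline
   regression (C-RCS): `value ~ RCS(age) + sex`, Harrell basis with knots
   at 2, 4, 22, 35, 75, 90 years, linear beyond the boundary knots. From
   the fitted spline: the analytic *difference per year* `f'(a)`, the
   *percent difference per year* `100 f'(a)/f(a)`, peak/minimum ages, and
   subject-level bootstrap 95% bands and peak-age intervals
   (B = 10,000 at full scale, 200 at desk scale).
3. **Association structure.** Pearson and partial (age- and sex-adjusted)
   correlations between features over sessions; correlation of
   per-pathway rate vectors between features within a cohort; correlation
   of development rates against aging rates per feature
   (gain-predicts-loss); anterior–posterior gradient fits — all with
   Benjamini–Hochberg FDR masks at q = 0.05.

A synthetic-data generator produces cohort tables with known ground-truth
curves, injected young-adult offsets, sex effects and noise, plus
parametric streamline bundles (straight tube, arc, fan; written/read as
TRK/TCK) and analytic scalar volumes (NIfTI), so the whole pipeline is
validated against closed-form expectations. The shape-feature,
volume-sampling and endpoint-probing modules operate on these same
containers for real tractograms and maps.

## Worked example

Generate a four-cohort study (500 subjects per cohort) whose FA-like
truth rises steeply in infancy, peaks at 30 y, then declines, with a
+0.03 young-adult acquisition offset; harmonize, fit, and summarize:

```r
library(bundlespan)

truth <- truth_record("AF_left", "FA", "poisson_like",
                      params = c(0.30, 0.012, 1/30),
                      ya_offset = 0.03, noise_sd = 0.012)
gen <- generate_feature_table(list(truth), default_cohorts(500), seed = 42)

est <- estimate_offset(gen$table)
est$offsets
#>    bundle feature target_cohort     offset
#> 1 AF_left      FA   young_adult 0.02848619

harm <- apply_offset(gen$table, est)
dat <- data.frame(age = harm$age, value = harm$FA, sex = harm$sex,
                  subject_id = harm$subject_id)
bt <- bootstrap_trajectory(dat, config = pipeline_config(B = 200, seed = 7))
bt
#> <trajectory_bootstrap> B = 200 used (0 dropped); extremum: peak at 30.53 y [29.33, 31.83]

bin_rates(bt$age_grid, percent_difference_per_year(bt$model, bt$age_grid))
#>           bin mean_pct_per_year
#> 1      infant            2.9705
#> 2 development            1.1634
#> 3 young_adult            0.0699
#> 4       aging           -0.3777
```

The estimated offset (0.0285) recovers the injected 0.03; the bootstrap
peak interval [29.3, 31.8] covers the true peak age of 30; and the binned
rates show the expected lifespan pattern — rapid infant increase, slower
development, plateau in young adulthood, decline in aging.

## Analysis workflow

The `analysis/` directory runs the pipeline as numbered stages, writing
tables under `results/`:

| script | stage |
|---|---|
| `01_simulate.R` | cohort table, truth JSON, TRK/TCK fixtures, NIfTI volumes |
| `02_shape_features.R` | ten shape features vs analytic geometry |
| `03_sample_features.R` | tract averages and endpoint probes |
| `04_harmonize.R` | young-adult offset estimation and removal |
| `05_trajectories.R` | C-RCS fits, bootstrap extrema, binned rates |
| `06_associations.R` | correlations, rate coupling, gradients |

Run them in order with `Rscript analysis/01_simulate.R` etc.; each prints
what it found and where it wrote its tables. `run_pipeline()` executes
the same stages as one call with a JSON run manifest (config snapshot,
file hashes, row counts) and is hash-reproducible under a fixed seed.

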