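# longvol

Longitudinal and paired-sample analysis of microbiome data in R.

Repeated sampling of the same subjects over time is what lets a microbiome
study separate within-subject change from between-subject heterogeneity —
but it also breaks the independence assumptions behind most off-the-shelf
statistics. longvol is a toolkit for that setting, aimed at analysts
working with per-sample metadata, feature tables (OTUs, taxa, sequence
variants), and precomputed beta-diversity distance matrices:

* **Temporal transforms** — first differences
  (ΔY<sub>t</sub> = Y<sub>t</sub> − Y<sub>t−1</sub>) of any numeric metric,
  first distances between a subject's successive samples read from a
  distance matrix, change from a baseline state
  (ΔY<sub>t</sub> = Y<sub>t</sub> − Y<sub>baseline</sub>), and change
  relative to a linked static reference sample (e.g. each infant against
  its mother's sample). Missing time points yield no delta — never an
  interpolated one.
* **Volatility charts** — control-chart statistics for a longitudinal
  metric: global mean, warning limits at ±2 SD, control limits at ±3 SD
  (computed across all samples), per-(group, state) mean ± SD aggregates,
  per-subject spaghetti trajectories, and outlier flags; emitted as a
  deterministic JSON plot spec plus a static figure.
* **Paired tests** — pre/post difference and distance testing between two
  states: Wilcoxon signed-rank within groups, Kruskal-Wallis plus pairwise
  Mann-Whitney U between groups with Benjamini-Hochberg correction
  (parametric equivalents via a flag).
* **Linear mixed-effects models** — y<sub>ij</sub> = X′<sub>ij</sub>β +
  Z<sub>ij</sub>b<sub>i</sub> + ε<sub>ij</sub> with per-subject random
  intercepts and optional random slopes on time, fit by REML, reported as
  treatment-coded coefficient tables (Estimate, SE, Z-score, two-tailed
  normal P value).
* **Feature volatility** — a supervised-regression pipeline (random forest
  by default) that predicts sample time from feature abundances: 4:1
  train/test split, cross-validated recursive feature elimination,
  normalized importances, held-out MSE/R², and per-feature descriptive
  statistics (mean, median, variance, SD, CV, net average change,
  cumulative increase/decrease).
* **Synthetic cohorts** — a seeded simulator generating metadata from the
  mixed-model equation, feature tables with planted time-trending features
  (Dirichlet-multinomial or Gaussian), and matching distance matrices.

Everything is exposed both as R functions and as `longvol` CLI subcommands
(`first-differences`, `first-distances`, `pairwise-differences`,
`pairwise-distances`, `linear-mixed-effects`, `volatility`,
`feature-volatility`, `jaccard`, `simulate`), each writing its outputs plus
a run-manifest JSON into an output directory.

## Worked example

```r
library(longvol)

sim <- simulate_cohort(
  cohort_design(50, 0:7, dropout_probability = 0.1, seed = 1),
  effect_spec(fixed_intercept = 2, fixed_slope = 0.5, random_slope_sd = 0.15,
              n_features = 100, n_planted = 5, feature_model = "gaussian"))

fit <- fit_lme(sim$metadata,
               lme_spec("y", fixed_effects = "delivery",
                        include_random_slope = TRUE))
print(fit)
#> Linear mixed-effects model (REML): y ~ delivery + month + (1 + month | .subject)
#> 364 observations over 50 subjects; converged: TRUE
#>
#> Fixed effects:
#>              Variable Estimate    SE Z-score P value
#>           (Intercept)    2.198 0.205  10.704  <0.001
#>  delivery [T.vaginal]   -0.321 0.297  -1.080    0.28
#>                 month    0.487 0.026  18.536  <0.001
#>
#> Random effects:
#>   Intercept (subject ID)      1.039
#>   Slope (change per state)    0.027
#>   Covariance (intercept, time) -0.024
#>   Residual variance           0.273

fv <- feature_volatility(sim$table, sim$metadata, regressor_config(seed = 2))
print(fv)
#> feature_volatility_result: 5 important features (random-forest)
#>   test-set accuracy: MSE = 1.178, R2 = 0.8063 (n = 73)
#>   top features by importance:
#>  feature importance      mean net_avg_change
#>    F0004  0.2166366  9.765750      -2.766785
#>    F0002  0.2147678  9.739870      -2.513087
#>    F0005  0.2099447 11.013843       3.113513
#>    F0001  0.1911677 10.972035       3.346125
#>    F0003  0.1674833  9.532592       2.913833
```

Reading the output: the mixed model recovers the planted population slope
(0.5) and intercept (2) within their standard errors and finds no delivery
effect (none was planted); the feature-volatility pipeline retains exactly
the five planted time-trending features, whose normalized importances sum
to one, and explains ~81% of held-out variance in sample time. The
`net_avg_change` column is the change in each feature's per-state mean
abundance from the first to the last state.

The same analyses from the shell:

```sh
longvol simulate --seed 1 --n-subjects 50 --states 0:7 --output sim/
longvol linear-mixed-effects --metadata sim/metadata.tsv --metric y \
    --state-column month --individual-id-column subject \
    --group-columns delivery --random-slope --output lme/
longvol feature-volatility --table sim/table.tsv --metadata sim/metadata.tsv \
    --state-column month --individual-id-column subject --seed 2 --output fv/
```

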