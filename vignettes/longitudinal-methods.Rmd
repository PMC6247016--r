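---
title: "Longitudinal and paired-sample analysis with longvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal and paired-sample analysis with longvol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longvol)
```

# Scope and data model

Longitudinal microbiome studies sample the same subjects repeatedly over
time, and the questions they raise — how fast does each subject's community
change, which features track host age, do experimental groups differ in
their trajectories — need methods that respect the within-subject
dependence structure. longvol works from three plain-text inputs:

* **sample metadata**: one row per sample, keyed by a unique sample ID,
  with a designated numeric *state* column (time, e.g. month of life) and a
  categorical *subject* column (the individual the sample came from);
* **feature tables**: samples × features abundance matrices (counts or
  relative frequencies), as dense TSV or BIOM;
* **distance matrices**: square, symmetric, hollow matrices of
  beta-diversity distances computed upstream (UniFrac, Bray-Curtis,
  Jaccard, ...).

Samples whose state or subject is missing are excluded from longitudinal
operations with a warning rather than an error, because real cohorts have
gaps: a subject that skips a visit should not invalidate the rest of the
analysis.

# Temporal transforms

If $Y_t$ is the value of a metric for one subject at state $t$, the **first
difference** is $\Delta Y_t = Y_t - Y_{t-1}$, computed at the fixed
intervals of the study's state grid — the sorted set of states observed
anywhere in the metadata. A subject missing the sample at $t$ or at the
grid state immediately before it gets *no* difference at $t$: gaps are
never bridged or interpolated, so every delta spans exactly one grid
interval and deltas need no per-unit-time normalization. (Encode states on
a common grid across subjects; a subject observed only at states no one
else shares contributes nothing.) The **first distance** is the analogue read from a
distance matrix: the beta-diversity distance between a subject's successive
samples, hence always nonnegative.

Both transforms accept a **baseline** variant, $\Delta Y_t = Y_t -
Y_{\mathrm{baseline}}$, measuring change relative to a fixed state (study
start, treatment time), and a **static-reference** variant in which each
subject's samples are compared against a linked, nonlongitudinal reference
sample — for example each child's stool samples against their mother's
sample, or fermentation samples against the inoculum.

Design choices worth knowing:

* States are compared by exact numeric equality; encode states consistently
  (e.g. always integers months).
* Replicate samples (same subject, same state) are an error by default;
  `"drop"` removes them, `"mean"` averages the metric. In distance mode
  `"mean"` is rejected because averaging rows of a distance matrix has no
  defined meaning here.
* Outputs are keyed by the *later* (moving) sample's ID. This makes the
  two-column output joinable back onto the metadata (`merge_series()`), so
  downstream tools that cannot operate on a distance matrix — the mixed
  model, the volatility chart — can analyze rates of beta-diversity change.

The correctness claim for this module is exact: the implementation is
compared, in the test suite, against independently coded brute-force loops
over 200 random subjects with random missingness, and the gap rule is
checked exhaustively.

# Paired difference and distance tests

For pre/post designs, `pairwise_differences()` pairs each subject's
observations at two chosen states and tests whether the median paired
difference departs from zero with the Wilcoxon signed-rank test
(zero differences are dropped, following Wilcoxon's original treatment, and
the dropped count is reported). `pairwise_distances()` instead looks up the
within-pair distance for each subject. Nonparametric tests are the default
throughout; `parametric = TRUE` switches to the one-sample t-test, one-way
ANOVA and pairwise t-tests. Between-group comparisons use Kruskal-Wallis
plus pairwise Mann-Whitney U with Benjamini-Hochberg correction — FDR
rather than Bonferroni because these are exploratory screens, and both raw
and corrected P values are reported. All tests are two-sided at
$\alpha = 0.05$.

Degenerate inputs are reported, not hidden: a group with fewer than two
paired subjects, or all-zero differences, yields a "not applicable" row
with the reason; when every value is tied the between-group statistic is
placed at its null center (P = 1).

# Linear mixed-effects models

The model is
$$y_{ij} = X'_{ij}\beta + Z_{ij} b_i + \varepsilon_{ij},$$
with $y_{ij}$ the $j$-th measurement on subject $i$, $X_{ij}$ the
fixed-effect covariates (group columns, declared interactions, and time),
$b_i \sim N(0, \Sigma)$ the per-subject random effects (intercept, and
optionally a slope on time), and $\varepsilon_{ij} \sim N(0, \sigma^2)$.
Random intercepts capture heterogeneity in starting level; random slopes,
heterogeneity in temporal trend — both are expected in longitudinal
microbiome data.

`fit_lme()` fits this by REML (default; ML is available for nested-model
comparison) via lme4, and reports each coefficient with its estimate,
standard error, Wald Z-score, and a two-tailed P value from the standard
normal — the reporting convention of statsmodels-style mixed-model tables.
Categorical covariates are treatment-coded against their lexicographically
first level and labeled `name [T.level]`, with interactions as
`a [T.x]:b [T.y]`; coefficients are presented in the canonical order
(intercept, main effects, declared interactions, then time). The
random-effect summary always contains four explicit rows: intercept
variance, slope variance, intercept–slope covariance, and residual
variance.

Two deliberate behaviors:

* A singular or non-converged fit is a *reported state*
  (`converged = FALSE`, with a warning suggesting dropping the random
  slope), not an exception — boundary fits are routine with small cohorts.
* No automated stepwise selection: the common practice of starting from all
  interactions and removing insignificant terms is left to the analyst,
  with `interactions =` giving precise control over what enters the model.

The test suite checks the frequentist calibration of this module by
simulation: over 100 synthetic cohorts of 100 subjects × 10 states (random
intercept SD 1, residual SD 0.5), each planted fixed effect's 95% Wald
interval covers the truth at a rate inside [0.90, 0.99]; and in the
degenerate zero-variance limit the fixed estimates agree with pooled OLS to
1e-3.

# Volatility charts

A volatility chart is a control chart overlaid with per-subject spaghetti
lines. `volatility_stats()` computes the metric's global mean and sample
standard deviation over **all** samples (not per group — group-specific
limits would hide exactly the between-group differences one wants to see),
places *warning limits* at mean ± 2 SD and *control limits* at mean ± 3 SD,
aggregates mean ± SD per (group, state) for the thick group-mean lines, and
flags every sample beyond either band. The sample (n − 1) standard
deviation is used, appropriate for small cohorts. Error bars are ± SD by
default (SEM via option).

`volatility_plot_spec()` emits a deterministic, JSON-serializable
description of the chart — group mean-line layers, one faded spaghetti
layer per subject, and exactly five horizontal rules (solid mean, dotted
warning pair, dashed control pair) — retaining the metric and grouping
fields so an interactive viewer can re-bind axes; `volatility_plot()`
renders the static figure. Under normality about 4.55% of samples should
fall beyond the warning limits and 0.27% beyond the control limits, and the
test suite confirms both fractions on 10,000 simulated values.

# Feature volatility

To find features whose abundance *predicts* time — and which are therefore
temporally informative rather than merely abundant — the feature-volatility
pipeline regresses the state column on the feature table:

1. a seeded random 4:1 train/test split (`group_by_subject = TRUE` splits
   whole subjects instead, preventing within-subject leakage; recommended
   for longitudinal designs, kept off by default to match the plain random
   split of the base procedure);
2. optional cross-validated hyperparameter tuning on the training set only;
3. cross-validated recursive feature elimination on the training set:
   each round removes the least-important 5% of remaining features
   (at least one), each candidate subset size is scored by 5-fold
   cross-validated MSE, and the size minimizing mean CV MSE is selected
   (ties resolved toward fewer features);
4. a final model — random forest with 100 trees by default; extra-trees,
   gradient boosting, and elastic net as alternates — trained on the
   selected features;
5. importances extracted and normalized to sum to one;
6. MSE and $R^2$ measured on the untouched test set;
7. descriptive statistics per retained feature;
8. a combined plot spec: per-feature volatility charts plus
   importance/statistic bar charts.

"Important features" means the features retained by RFE in the final
model. Importance does **not** imply statistical significance; only
features from accurate models (respectable held-out $R^2$) are likely to
be temporally informative, which is why accuracy is always reported beside
the importances.

The per-feature descriptive statistics are: mean, median, variance, SD and
coefficient of variation over all samples (CV is reported missing when the
mean is zero), plus change statistics computed on the per-state mean
profile $m_f(t)$ with states ascending: net average change
$m_f(t_k) - m_f(t_1)$, cumulative average increase
$\sum_j \max(0, m_f(t_{j+1}) - m_f(t_j))$ and cumulative average decrease
$\sum_j \min(0, \cdot)$, so increase + decrease = net always. Computing
changes on global per-state means (rather than averaging per-subject first
differences) is a deliberate choice; the two coincide for balanced designs.

Abundances are used as given; `relative_frequency = TRUE` closes counts to
per-sample proportions first. A seed is required — there is no silent
nondeterminism, and a fixed seed reproduces importances, accuracy and
statistics bit for bit.

# The synthetic cohort generator

`simulate_cohort()` is the package's test bed: it generates metadata whose
metric follows exactly the mixed-effects model above (so planted
$\beta$, $\Sigma$, $\sigma^2$ are known), a feature table with planted
time-trending features, and a matching distance matrix, all reproducible
from one seed. Two feature models are provided:

* **dirichlet** — Dirichlet-multinomial counts around state-dependent mean
  compositions, mimicking microbiome compositionality (sparse integer
  counts, fixed sequencing depth); planted features trend on the
  log-abundance scale; the paired distance matrix is Jaccard.
* **gaussian** — independent truncated-Gaussian abundances, with planted
  features' means moving monotonically across the state range by a chosen
  multiple of the noise SD; the paired distance matrix is Euclidean. This
  is the model used for the supervised-regression benchmarks, where
  independent noise features and a controlled effect size are the point.

The `ecam_like_design()` preset mirrors a small early-life cohort — 43
subjects, monthly sampling over months 0–24, two delivery-mode groups, two
diet groups, moderate dropout — as a realistic default scale for
demonstrations.

What the simulator does *not* emulate: taxon-taxon correlation structure,
overdispersion beyond Dirichlet-multinomial, technical batch effects, or
library-size variation. Tests passing on these synthetic cohorts therefore
demonstrate algorithmic correctness and statistical calibration under the
stated generative models, not performance guarantees on any particular real
data set.

# Numerical conventions and problem sizes

* Writers emit TSV with LF terminators and 10 significant digits; readers
  are left inverses of writers at that precision, and a write–read–write
  cycle is byte-stable.
* Distance matrices are validated symmetric within 1e-8 and hollow;
  Jaccard presence is strict `> 0` with a configurable detection threshold
  defaulting to 0.
* JSON plot specs are serialized with fixed field order and 10 significant
  digits, so identical inputs give byte-identical files.
* The simulation-based checks use: 200 subjects × 10 states for the
  transform oracles; 100 replicates of 100 subjects × 10 states for
  mixed-model coverage; 10,000 values for the control-chart tail
  fractions; and 20 seeds of 50 subjects × 8 states with 5 planted among
  100 features (effect 3× the noise SD) for the feature-volatility
  benchmark, with a 6-seed version of the same conditions in the
  acceptance script. These sizes were chosen to make the Monte-Carlo
  bands tight enough to be meaningful while keeping a full run of the
  suite comfortably interactive.

# A worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(
  cohort_design(50, 0:7, dropout_probability = 0.1, seed = 1),
  effect_spec(fixed_intercept = 2, fixed_slope = 0.5, random_slope_sd = 0.15,
              n_features = 100, n_planted = 5, feature_model = "gaussian"))

# rate of change of the metric within subjects
fd <- first_differences(sim$metadata, "y")

# population trend with per-subject random intercepts and slopes
fit <- fit_lme(sim$metadata,
               lme_spec("y", fixed_effects = "delivery",
                        include_random_slope = TRUE))
print(fit)

# which features predict time?
fv <- feature_volatility(sim$table, sim$metadata, regressor_config(seed = 2))
print(fv)
```

# Known limitations

* Gaussian responses only: no generalized or zero-inflated mixed models.
* No interpolation or rate normalization of unequal sampling intervals.
* The volatility chart's limits assume the pooled sample is a sensible
  reference population; with strong time trends the global SD mixes trend
  and noise.
* Paired tests handle exactly two states; more belongs to the mixed model.
* The CLI's plot output is static (PDF) plus the declarative JSON spec;
  interactive rendering is left to downstream viewers.
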