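---
title: "Methods: seasonality analysis of longitudinal multi-omics cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seasonality analysis of longitudinal multi-omics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic cohort generator does and does not emulate,
the numerical choices, and the places where the design was genuinely open
and a decision had to be made.

## The seasonal model

Every analyte is analyzed on the day-of-year circle, `t ∈ [1, 365]`.
Calendar dates are mapped by `day_of_year()`, with leap-day 366 clamped to
365 so that all years share one circle. The per-analyte model is a
penalized Gaussian regression

$$y_{ij} = \beta_0 + \beta_{IRIS}\,\mathrm{IRIS}_i + \beta_{BMI}\,\mathrm{BMI}_i
  + f(t_{ij}) + b_i + \varepsilon_{ij},$$

with three ingredients:

* **Cyclic cubic regression spline** `f`: value, first and second
  derivative match at the two ends of the period, so fitted annual curves
  wrap smoothly from December 31 to January 1. The basis and its
  integrated-squared-second-derivative penalty come from
  `mgcv::smoothCon()`; the coefficients are curve values at the knots, so
  constants are exactly representable and the penalty null space is the
  constant. Default `n_basis = 10` evenly spaced knots over `[1, 366)` — a
  conventional default for annual smooths; the fit is insensitive to
  moderate changes because the penalty controls the effective flexibility.
* **Subject random intercepts** `b_i`, implemented as ridge-penalized
  subject indicator coefficients. This is exactly the penalized-regression
  representation of a Gaussian random intercept and keeps every fit a
  single linear solve, at the cost of treating the selected ridge as fixed
  (no REML integration over the variance component).
* **Linear covariates**, mean-centered, so the fitted annual curve at
  covariate zero is the population-average curve. The default covariate
  set is `group` (IR indicator) and `bmi` for the seasonality scan, and
  `age` + `bmi` for the group-difference stage (there the group is the
  thing under test). Covariates that are constant within the fitted rows
  (e.g. group inside a single-group fit) are dropped automatically.

Smoothing `λ` and the subject ridge are selected jointly by **GCV** over
log-spaced grids (defaults: 30 points in `1e-4..1e6` for `λ`, 5 points in
`1e-2..1e2` for the ridge). Grid search is deterministic, trivially
reproducible and cheap here because the design factorizations are shared
across all analytes measured on the same visits. Ties in the GCV score —
which occur for noiseless data, where every grid point fits perfectly —
resolve to the *largest* penalties, i.e. the smoothest representation.
For the seasonality scan the GCV degrees-of-freedom inflation
`gcv_gamma = 1.4` is used, the customary correction for GCV's tendency to
undersmooth; the differential stage uses `gcv_gamma = 1` (see below).

### The seasonality test

The hypothesis "this analyte has an annual component" is tested by
comparing the model above against the same model without `f`. The default
(`pvalue_method = "lrt"`) is the exact Gaussian likelihood-ratio F-test of
the *unpenalized* spline block: both models share the covariates and the
subject ridge chosen for the null model, the spline enters with its full
`n_basis − 2` constrained degrees of freedom, and the statistic is the
standard nested-model F. The alternative (`pvalue_method = "edf"`) is a
chi-squared on the penalized deviance difference with
`max(1, round(EDF of smooth))` degrees of freedom.

This choice was genuinely open, and we settled it by simulation-based
calibration, which we regard as the operational contract of the test: on
null analytes (no seasonal signal, subject baselines plus noise at the
package's desk-scale cohort) the empirical type-I error at `α = 0.05`
should sit near 0.05. The EDF-based chi-squared inherits the optimism of
GCV smoothness selection — the data pick their own degrees of freedom, and
the chi-squared does not know that — and over-rejects even with the
`γ = 1.4` correction, while the F-test of the fixed-dimension spline block
is calibrated essentially by construction. The acceptance suite verifies
both calibration (500 null analytes) and power (200 analytes at
amplitude/noise = 3, where rejection should be near-certain). No
multiplicity correction is applied across analytes by default — the
selection rule for downstream clustering is raw `p ≤ 0.05` — but
`p.adjust()` on the scan table is one line for users who want FDR control.

### Curves and bands

`evaluate_curve()` returns the fitted annual curve with the pointwise 95%
band `fit ± 1.96·sd`, where `sd(t) = sqrt(x_t' V x_t)` propagates the
coefficient covariance `V = σ̂²(XᵀX + P)⁻¹` through the prediction row
`x_t`. The prediction row sets centered covariates to zero and gives every
subject indicator weight `1/n_subjects`: the curve is the cohort-average
trajectory, including the average of the shrunken subject effects. That
convention matters numerically: with a weak ridge the intercept and the
subject indicators are nearly collinear, and a prediction row that zeroes
the subject block inherits that ill-conditioning as an exploding variance,
whereas the subject-averaged functional stays identifiable at any ridge
strength.

## Pattern discovery

Clustering operates on **standardized fitted curves** — each significant
analyte's curve evaluated on days 1..365, z-scored across days — not on raw
spline coefficients, which are basis-dependent. Constant curves cannot be
z-scored and are excluded with a recorded reason.

`fuzzy_cmeans()` is Bezdek's alternating optimization with Euclidean
distances, fuzzifier `m = 2` by default (the common choice; `m → 1⁺`
approaches hard k-means, large `m` flattens memberships), convergence when
the objective moves less than `1e-9` or after 1000 iterations, and 10
seeded random restarts keeping the best objective — C-means is sensitive to
initialization and restarts are cheap at this scale. A curve at
(numerically) zero distance from a centroid takes membership 1 there; the
zero threshold is relative (`1e-12` of the row's largest squared distance)
so that projecting a centroid onto its own model returns an exact unit
vector.

`select_k()` scores each `k` by the average silhouette width of the
*hardened* (argmax) partition; singleton clusters score 0 by the standard
convention. The within-cluster sum of squares is reported alongside for an
elbow reading, but the chosen `k` is the silhouette argmax. The scan
starts at `k = 2` because the silhouette is undefined for a single
cluster. The fuzzy-silhouette variant, and per-ome cluster atlases, are
deliberately out of scope.

`project_membership()` evaluates the membership formula against *fixed*
centroids — this is how external streams (clinical labs, meteorology,
pollen) are related to the learned omics patterns without refitting the
clustering.

## Interval-wise group differences

For each analyte the two groups get independent seasonal fits on a shared
annual grid of `T` points, and each of the `T − 1` intervals gets the
studentized trapezoid-area difference statistic (areas over the unit
interval; antisymmetric under group exchange; defined as 0 when both the
numerator and both standard errors vanish). The null is built by
relabeling **subjects** `B` times — group is a subject-level attribute with
repeated measures, so all of a subject's visits move together; a literal
per-visit relabeling is available as `unit = "sample"`. Each interval's
p-value is the fraction of all `B·(T−1)` pooled permuted statistics more
extreme in the observed statistic's own direction (greater for
non-negative observed values, smaller for negative). The comparand is the
*observed* statistic: one-sided exceedance in the observed direction,
combined with the halved threshold below, is the reading under which the
overall test is a coherent two-sided procedure. No pseudo-count is added,
so p = 0 is possible; a `+1`-style smoothing can be had by
post-processing, but the formula is kept exact by default.

Within each analyte the interval p-values are BH-adjusted and intervals
with adjusted p `< α/2` are called significant; BH is applied per feature
across intervals (applying it pooled across features is a configuration
away, but the per-feature form is the default because interval calling is
a per-feature decision). Features are classified `global` when every
interval is significant, `partial` when at least one but not all are, and
`none` otherwise; contiguous significant runs are reported as day ranges,
with runs touching both year ends merged across the day 365 → 1 boundary.

Two desk-scale choices keep `B = 200`–`1000` refits affordable: the grid
defaults to `T = 52` (weekly resolution; `T = 365` is a parameter change
away and all outputs state their grid), and the differential
`model_spec()` uses a coarser penalty grid. The engine also precomputes
per-subject cross-product blocks, so each permutation refit is a sum of
small matrices plus one factorization per grid point. `gcv_gamma = 1`
(the plain GCV) is used here rather than 1.4: the permutation null runs
the identical procedure, so anti-overfit conservatism buys no validity and
measurably costs power to detect sub-annual windows.

The type-I behaviour of the whole cascade (any-interval family-wise rate
near `2α` on null analytes) and the recovery of injected 90-day windows
(Jaccard overlap of called and true day sets) are checked in the test
suite at the desk-scale study conditions: 40 subjects × 12 visits, effect
twice the residual noise, `T = 52`, `B = 200`, 25 replicates.

## Richness seasonality

`chao1()` implements both the classic (`S_obs + F1²/(2F2)`) and the
bias-corrected (`S_obs + F1(F1−1)/(2(F2+1))`) estimator; the
bias-corrected form is the default because it is defined when doubletons
are absent. No rarefaction is applied before estimation; a
sequencing-depth covariate can be added to the seasonality model through
the ordinary covariate mechanism. `aggregate_taxa()` sums counts within
lineage groups (unmapped taxa become `"unclassified"`), conserving
per-sample totals, so richness can be assessed at genus through phylum
level. `diversity_seasonality()` feeds the per-sample Chao1 series into
the same cyclic-spline model and reports, besides the seasonality p-value,
the winter-vs-summer contrast of the fitted curve: mean over days
{1..60, 335..365} minus mean over days {152..244}, positive when the
community is richer in winter.

## The synthetic cohort generator

The generator is the package's test bed and defines its study conditions.
It emulates:

* a multi-year design with visits drawn uniformly over the calendar
  (desk-scale default 40 subjects × 3 years × 4 visits; a 105-subject
  preset matches the published cohort's size), subject-level IR/IS labels,
  BMI ~ N(28, 4²) kg/m², ages uniform in 25–75;
* two seasonal archetypes as von Mises shaped bumps on the circle with
  centers at day 115 (late April) and day 350 (December) and concentration
  1.42, giving a full width at half maximum near 120 days — the December
  bump automatically places its trough in March–July; a `bimodal` kind
  averages the two;
* analyte values as subject baseline + amplitude × archetype (with a
  per-feature phase shift drawn once from ±`phase_jitter` days) + optional
  BMI term + group effect + Gaussian noise. Differential features switch
  their IR-minus-IS effect on inside a day window with 15-day cosine
  ramps; window-free differential features are shifted all year;
* taxon counts as per-visit multinomials over a community with a core of
  always-present taxa and a seasonal block whose presence probability
  rises from `base_occupancy` in summer to a winter ceiling solved from
  the requested winter/summer expected-richness ratio (default 1.5);
  infeasible ratios are a validation error. Default community: 150 taxa,
  depth 10,000 reads, log-normal abundance profile; the lineage map packs
  genera 5-per-family, families 3-per-order, and so on.

The defaults — amplitude 3, unit noise, unit subject SD, effect size 2 for
differential features — put planted signals at signal-to-noise 3 and 2,
strong but not degenerate values at which a competent method should
succeed while a miscalibrated one still fails visibly.

What the generator does **not** emulate: assay-specific noise (count
overdispersion in RNA-seq, LC-MS batch drift, detection limits),
missingness beyond an optional uniform rate, correlated features,
subject-level phase differences, secular (non-annual) trends, and
compositional artifacts in the taxon table. Passing tests therefore show
that the machinery is correct and calibrated under clean Gaussian
repeated-measures seasonality — not that real cohort data meet those
assumptions. One visible consequence: with only 3–5 phyla, every phylum is
present in every sample and richness at the highest ranks is constant, so
the generator only produces detectable richness seasonality at genus,
family and order level, while real communities can show it higher up.

## Numerical choices and edge cases

* Penalized solves use Cholesky with a pseudo-inverse fallback, so the
  zero-penalty corner (`λ = ridge = 0`, where intercept and subject
  indicators are collinear) still returns the unique least-squares
  *projection*; the test suite pins this to `lm` to `1e-8`.
* Perfect fits: when the null model already has (numerically) zero
  residual sum of squares there is no seasonal evidence and the p-value is
  1; a zero-residual full model under a non-trivial null gives p = 0.
* Analytes with fewer than `n_basis + n_covariates + 2` complete
  observations are reported as "not fitted" skip objects, not errors;
  missing values are dropped per analyte.
* All day coordinates in outputs are 1-based inclusive in `[1, 365]`;
  intervals are `[t, t+1]` on the stated grid.
* Every stochastic step (generator, restarts, permutations, pipeline
  stages) takes an explicit seed, and `run_all()` derives all stage seeds
  from the single configuration seed, so reruns reproduce output
  checksums.

## Known limitations

* The subject ridge is selected by GCV and then treated as fixed; there is
  no REML uncertainty propagation for the variance components, and the
  Gaussian working model is used for all omes (count-native models for
  microbiome abundances are out of scope; values are assumed normalized
  upstream).
* Group-curve standard errors understate between-subject uncertainty when
  the ridge is strong; the permutation null, not the Gaussian band, is the
  inferential basis of the interval test.
* The silhouette criterion cannot express "one cluster"; structureless
  inputs manifest as uniformly low silhouettes rather than `k = 1`.
* Interval statistics are strongly dependent across intervals within an
  analyte (a group-mean shift moves the whole year), which the pooled
  permutation null absorbs but which makes per-interval p-values
  unsuitable for reading as independent evidence.
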