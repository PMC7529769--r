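# seasonomics

Seasonality analysis of longitudinal multi-omics cohorts: detect analytes
that fluctuate over the calendar year, discover the dominant annual
patterns, relate external data streams to them, test whether
insulin-resistant (IR) and insulin-sensitive (IS) participants follow
different annual trajectories, and quantify seasonal shifts in microbial
richness. The package is aimed at biostatisticians working with
repeated-measures cohort data (transcripts, proteins, metabolites,
cytokines, clinical labs, 16S taxon counts) collected at visits spread over
several years.

## The models

**Per-analyte seasonality.** Each analyte `y` is modeled on the day-of-year
circle `t ∈ [1, 365]` as

```
y_ij = β₀ + β_IRIS·IRIS_i + β_BMI·BMI_i + f(t_ij) + b_i + ε_ij
```

where `f` is a cyclic cubic regression spline (value and first two
derivatives match across day 365 → day 1), `b_i` is a Gaussian subject
random intercept represented as ridge-penalized subject indicators, and the
spline roughness penalty and subject ridge are selected by GCV over a grid.
Seasonality is tested by the Gaussian likelihood-ratio (F) test of the
spline block against the no-season model; analytes with `p ≤ 0.05` enter
pattern discovery. Fitted annual curves carry 95% bands
(`fit ± 1.96·sd`, sd propagated from the coefficient covariance).

**Pattern discovery and projection.** Standardized fitted curves
(z-scored across days) are clustered by fuzzy C-means
(memberships `u_ij = 1/Σ_l (d_ij/d_il)^{2/(m−1)}`, fuzzifier `m = 2`),
with the number of patterns `k` chosen by the average silhouette width over
`k = 2..10`. New curves — clinical labs, meteorology, pollen counts — are
*projected* onto the fixed centroids, giving each stream a membership in
`[0, 1]` per seasonal pattern.

**Interval-wise group differences.** For each analyte, group-specific
spline fits on a `T`-point annual grid give, per interval `[t, t+1]`, the
studentized area statistic

```
stat = (A₁ − A₂) / sqrt(((SE₁ₜ+SE₁ₜ₊₁)/2)² + ((SE₂ₜ+SE₂ₜ₊₁)/2)²)
```

whose null distribution is built by permuting group labels across subjects
`B` times and pooling all `B·(T−1)` permuted statistics. Interval p-values
are BH-adjusted and called significant below `α/2`; features are classified
`global` (all intervals), `partial` (some) or `none`.

**Richness seasonality.** Chao1
(`S_obs + F1(F1−1)/(2(F2+1))`, bias-corrected by default) per sample at any
taxonomic level, with the same cyclic-spline model fitted to the richness
series and a winter-vs-summer fitted contrast.

A ground-truthed synthetic cohort generator (`simulate_cohort()`) emulates
the study design — quarterly visits spread uniformly over multiple years,
two seasonal archetypes peaking in late April and December, IR/IS effects
active over the whole year or a sub-window, winter-boosted taxon richness —
so every stage is testable without cohort data.

## Worked example

```r
library(seasonomics)
design <- cohort_design(n_subjects = 40, n_years = 3, visits_per_year = 4,
                        seed = 42)
sim <- simulate_cohort(design, default_feature_specs(60), taxa = TRUE)
scan <- seasonality_scan(sim$data[c("sample_id", "feature_id", "ome", "value")],
                         sim$visits)
scan
#> Seasonality scan: 60 features (60 fitted), 45 with p <= 0.05
head(scan$table[order(scan$table$p_value),
                c("feature_id", "p_value", "edf", "peak_day", "amplitude")], 4)
#>    feature_id      p_value      edf peak_day amplitude
#> 8       F0008 1.194383e-75 5.484326      104  3.101720
#> 21      F0021 5.121945e-73 6.316482      358  3.448573
#> 9       F0009 1.397957e-71 5.484326      110  3.051247
#> 5       F0005 8.951088e-71 5.484326      120  3.015947
```

45 of 60 features are detected as seasonal (the panel contains 36 seasonal,
6 bimodal and 18 non-seasonal/differential features); the strongest hits
peak in mid-April (days 104–120) and early December (day 358), matching the
two planted archetypes, with fitted amplitudes near the simulated value 3.

```r
curves <- standardize_curves(scan)   # z-scored fitted curves, p <= 0.05
ks <- select_k(curves, 2:6, seed = 42)
ks
#> Cluster-number selection (average silhouette):
#>  k avg_silhouette within_ss
#>  2      0.6857029 3119.3849
#>  3      0.7086465 1581.5468
#>  4      0.7710843  485.7124
#>  5      0.6569740  361.5891
#>  6      0.4666627  305.1704
#> chosen k = 4
```

On this mixed panel the silhouette criterion finds four shapes — the two
archetypes, the bimodal features, and the near-flat false positives. On a
pure two-archetype panel it selects `k = 2` (that recovery is what
`scripts/acceptance.R` measures).

```r
ds <- diversity_seasonality(sim$counts, sim$visits, sim$taxonomy, "genus")
#> richness seasonality: p = 3.73e-197, winter-summer contrast = +28.6 taxa
```

The winter-boosted community is correctly detected: about 29 more genera in
the fitted winter curve than in summer, with an overwhelming seasonality
p-value.

The `analysis/` directory holds the full numbered workflow
(`01_simulate.R` … `06_diversity.R`); each script reads its predecessors'
tables from `results/` and states what it found. `run_all()` chains the
same stages programmatically from a single seeded configuration.

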