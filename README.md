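# moltclock

Metabolic aging clocks and population-noise statistics for molted laying
hens.

## The problem

Induced molting — a short period of severe caloric restriction applied to
aging laying hens — pauses reproduction and then restores egg production
close to youthful levels. Whether that recovery reflects genuine systemic
rejuvenation can be asked quantitatively with plasma metabolomics: do
age-tracking metabolites in molted hens move back toward younger values,
and does the *population heterogeneity* of the metabolome (a hallmark of
aging) shrink after the molt?

`moltclock` implements the complete analysis chain for a two-arm
longitudinal design (control vs molted, ages 21–33 months, daily egg logs,
plasma metabolomics at reference ages, a 9-channel cytokine panel), for
anyone analyzing such cohorts or studying the statistical behavior of the
procedures themselves:

* **Phenotypes** — monthly laying efficiency (eggs/days), sterility
  (21 consecutive zero-egg days), mortality, and their association
  (Fisher exact, binomial survival comparison).
* **Aging biomarkers** — per timepoint-pair two-tailed Mann–Whitney tests
  across all features, Benjamini–Hochberg FDR at *q* ≤ 0.1 within each
  pair, OR-pooling across pairs, and a strict median-monotonicity filter.
* **Laying biomarkers** — Spearman correlation of each feature with the
  hen's sampling-month efficiency across pooled control samples, BH-FDR.
* **Metabolic age** — reference-set z-scoring, a control-derived PCA age
  axis (PC1 oriented old-right, group medians as metabolic-age
  representatives), and a control-trained random-forest age regressor
  (500 trees, seeded) transferred to molted hens; leave-one-out
  efficiency prediction with an optional LASSO screen.
* **Metabolic noise** — the median of per-feature coefficients of
  variation (σ/μ) per group and age, with hen-label permutation tests,
  plus reproduction-noise trajectories compared by a paired within-hen
  slope permutation.
* **A cohort simulator** — `simulate_cohort()` generates all three data
  kinds with planted, queryable ground truth (which features age, which
  track fecundity, the true attenuation), so every procedure is validated
  by parameter recovery.

The central statistic: for a (group, age) cell with intensity matrix
`X` (features × hens), each feature's noise is `CV = sd(x)/mean(x)` and
the cell's **metabolic noise** is `median(CV₁ … CV₆₉₃)` — unitless and
scale-invariant, so features spanning orders of magnitude pool cleanly.
Significance comes from permuting hen labels and recomputing the whole
statistic each time; p = (# permutations at least as extreme) / (#
permutations).

## Worked example

```r
library(moltclock)
library(dplyr)

cohort <- simulate_cohort(sim_config(seed = 1))
eff    <- monthly_efficiency(cohort$laying)

aging  <- select_aging_biomarkers(cohort$metabolites)
laying <- select_laying_biomarkers(cohort$metabolites, eff)
nrow(aging); nrow(laying)
#> [1] 244
#> [1] 363
selection_performance(aging, cohort$truth$aging_features, 693)
#> # A tibble: 1 × 4
#>   n_selected n_true sensitivity precision
#> 1        244    208       0.995     0.848
```

Of 693 simulated features, the screen selects 244 aging biomarkers and
recovers 99.5% of the 208 planted ones at 85% precision — the same
procedure and yield regime as a ~210-marker screen on real plasma data.

```r
noise <- noise_trajectory(cohort$metabolites, n_perm = 1000, seed = 2)
as_tibble(noise)
#> # A tibble: 7 × 4
#>   group   age_months median_cv n_samples
#> 1 control         21     0.257        12
#> 2 control         23     0.274        12
#> 3 control         27     0.294        12
#> 4 control         33     0.325        12
#> 5 molted          21     0.260        12
#> 6 molted          27     0.202        12
#> 7 molted          33     0.207        12
attr(noise, "comparisons")
#>   age_months observed_diff p_value n_perm
#> 1         21       0.00279     0.7   1000
#> 2         27       0.0919      0     1000
#> 3         33       0.118       0     1000
```

Control noise climbs steadily with age (0.26 → 0.33) while molting drops
it below baseline (0.26 → 0.20); the hen-permutation test finds no group
difference before the molt (p = 0.7) and a clear one after (p < 0.001,
i.e. 0 of 1000 permutations as extreme).

```r
model <- train_age_regressor(cohort$metabolites, aging$feature_id, seed = 3)
median_predicted_ages(predict(model, cohort$metabolites))
#> # A tibble: 7 × 4
#>   group   age_months median_predicted
#> 1 control         21             21.8
#> 2 control         23             24.2
#> 3 control         27             26.9
#> 4 control         33             32.3
#> 5 molted          21             23.0
#> 6 molted          27             25.3
#> 7 molted          33             27.7
```

The control-trained forest orders every group correctly, places the
held-out 23-month validation controls between their neighbors, and assigns
molted hens an initially *older* age (23.0 at 21 months — the treated
subset deliberately excluded the top layers) but a clearly *younger* final
age (27.7 at 33 months): the molted arm traverses fewer metabolic months
than its chronological year, the slower-aging readout. (Forest boundary
shrinkage compresses the absolute span; see the methods vignette.)

`run_pipeline(sim_config(seed = 1), "out/")` executes the whole chain and
writes every table plus a machine-readable `summary.json`; two runs with
the same config are byte-identical. `autoplot()` methods cover the age
axis, noise trajectories, and prediction evaluations.

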