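---
title: "Metabolic aging, rejuvenation, and population noise in molted laying hens: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic aging, rejuvenation, and population noise in molted laying hens: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moltclock)
library(dplyr)
```

## The scientific setting

Induced molting — an acute period of severe caloric restriction applied to
aging laying hens — pauses reproduction, sheds feathers, and, once the hens
return to ad libitum feeding, restores egg production close to the level of
much younger birds. `moltclock` implements the computational side of a
longitudinal study design built around that phenomenon: two arms of hens
(untreated controls and a molted group) are followed from 21 to 33 months of
age with daily egg logs, plasma metabolomics at reference ages (21, 27, 33
months, plus a control-only validation timepoint at 23 months), and a small
cytokine panel. The analyses ask three questions:

1. **Which metabolite features track age, and which track reproduction?**
   (FDR-screened aging and laying biomarkers.)
2. **Does molting slow metabolic aging?** (A control-trained metabolic-age
   axis and regressor applied to molted hens.)
3. **Does molting reduce population heterogeneity?** (Coefficient-of-variation
   noise statistics with permutation nulls.)

Because the raw plasma tables of the motivating study are not deposited under
a named accession, the package ships a cohort simulator
(`simulate_cohort()`) that reproduces the *statistical structure* of such a
study with queryable planted ground truth, so every downstream procedure can
be validated by parameter recovery rather than by eye.

## The biomarker screens

**Aging biomarkers.** For each pair of reference ages (21–27, 21–33, 27–33
months) every feature receives a two-tailed Mann–Whitney p-value comparing
the control samples at the two ages. Each pair's full p-value list is
Benjamini–Hochberg corrected at `q_cutoff = 0.1`, features significant in at
least one pair are pooled (an OR rule), and features whose three control
group medians are not strictly monotone in age are removed. The monotonicity
filter is applied to raw-intensity medians; z-scoring is a per-feature
monotone affine map, so the verdict is unchanged (asserted by a property
test). Strictness is deliberate: a tie between medians carries no direction,
and with continuous intensities ties are measure-zero anyway.

**Laying biomarkers.** Control samples are pooled across all timepoints and
each is paired with its hen's laying efficiency (eggs per day) in the month
of blood sampling. Features are screened by Spearman correlation against
efficiency with BH correction over the full feature list. The cutoff
defaults to 0.1 for symmetry with the aging screen; it is a parameter.

**Common markers.** The intersection of the two sets, filtered for
consistency with the hypothesis that molting slows aging while improving
performance. The package operationalizes "consistent" as two toggleable
conditions: (a) the efficiency correlation must oppose the age direction
(higher efficiency looks younger), and (b) the molted group's median at the
last timepoint must lie strictly between the control medians at the first
and last timepoints. Both are one reading of a qualitative requirement and
are flagged as such in `common_markers()`.

## Metabolic age

All modelling happens on z-scores computed with *reference-set* constants:
`zscore_normalize()` centers and scales each feature by its mean and SD over
a stated reference set (the training controls) and applies those constants
to every other sample. Held-out and transferred samples therefore never
influence the normalization — the only leakage-safe reading of a
train/test discipline.

The **PCA age axis** is fitted on control samples of the aging-biomarker
submatrix; all samples (including molted) are projected onto the
control-derived axes. The PC1 sign is fixed deterministically so the control
median coordinate at 33 months exceeds the one at 21 months: older is always
to the right. Group medians along PC1 act as metabolic-age representatives;
`median_axis_aging()` measures a group's displacement between two ages, and
`axis_aging_contrast()` tests the control-vs-molted difference of those
displacements by permuting group labels within each age.

The **age regressor** is a random forest (500 trees, one third of the
features tried per split, unlimited depth, mandatory seed) trained
exclusively on control samples at the three reference ages. Molted samples
are normalized with control constants and predicted; the group's median
predicted age per timepoint, and the span from 21 to 33 months, read out the
aging rate. Forest hyperparameters are frozen rather than tuned: the readout
is a rate comparison, not a leaderboard.

A caveat the simulations make explicit: regression forests shrink
out-of-sample predictions toward the training mean, and at boundary ages the
shrinkage is one-sided. At the simulator's default noise level a planted
8-month metabolic span reads out as roughly 5–7 months. The hierarchy (older
groups predicted older) is extremely robust; the absolute span is
conservative. Interpreting spans therefore requires either a shrinkage-aware
baseline (compare against controls predicted out-of-bag) or, as here,
reporting the planted-versus-recovered relationship openly.

**Efficiency prediction** uses the same machinery with laying efficiency as
the response. `loo_predict_efficiency()` runs a strict leave-one-out loop —
normalization constants, the optional LASSO screen (nonzero coefficients at
the cross-validated penalty), and the forest are all refit without the
held-out sample. The marker set itself is fixed before the loop, matching
the stated order of operations of the study design; this is mildly
optimistic (selection saw all control samples) and is documented rather than
hidden. `predict_efficiency_transfer()` applies a control-trained model to
molted hens; because transfer claims in this setting are range-level, the
result carries a range-capture rate rather than a pointwise error.

## Noise statistics

The coefficient of variation of a feature across the hens of one (group,
age) cell is `sd/mean` (sample SD, n−1 denominator — with 12 hens the
choice is material). The cell's **metabolic noise** is the *median* of its
per-feature CVs. CVs are unitless and scale-invariant, which is what lets
hundreds of features spanning four orders of magnitude be combined; the
package enforces computation on raw positive intensities (z-scored input has
near-zero means and is rejected with an informative error).

Significance between two groups at one age uses a hen-label permutation:
hens are reshuffled between the groups and the *entire* median-of-CV
statistic is recomputed per permutation — statistic-level permutation, not
per-feature pooling. Reported p-values are exactly `n_extreme / n_perm`, so
zero is possible; raise `n_perm` when resolution matters.

**Reproduction noise** is the CV of individual monthly laying efficiencies
per group and month. The post-molt window comparison
(`reproduction_slope_test()`) contrasts the OLS slope of the two groups'
noise trajectories over a window in which every hen is alive, with a paired
null that shuffles each hen's values across months *within that hen* —
longitudinal data demand a within-subject null. One directionality caveat:
the default mode takes the rejection direction from the observed sign, which
makes the null rejection rate approximately twice the nominal level (a
documented property of sign-picked one-sided permutation tests). When the
direction is known a priori, pass `alternative = "greater"` or `"less"`,
which is exactly nominally calibrated and is what the package's own
calibration tests measure.

**Cytokine panel.** Each of the nine channels is averaged over the hens of a
cell and normalized by that channel's group baseline at 21 months (so every
baseline median is exactly 1 by construction); the cell's representative
measure is the median of the nine normalized channels, compared between
groups by hen-label permutation with baselines held fixed.

## The cohort simulator

`simulate_cohort()` generates, per arm of `n_hens_per_group = 32` hens:

* **Latent fecundity**: a logistic decline in hen age with a hen-level
  random intercept (median efficiency ≈ 0.82 at 21 months, declining
  `efficiency_decline_per_month = 0.02` near the start — the regime of an
  aged commercial flock). Molted hens drop to zero fecundity over months
  22–23 and restart from a tighter intercept centered on
  `molt_recovery_efficiency = 0.9`, keeping half of their pre-molt
  deviation (hen quality persists through the molt) and declining at
  `molt_attenuation = 2/3` of the control rate.
* **Eggs, sterility, death**: daily Bernoulli egg events; a monthly
  reproductive-collapse hazard rising with age (calibrated so roughly 40–50%
  of controls turn sterile by 33 months and about a third of the arm dies,
  versus a much lower post-molt hazard producing mortality in the low teens
  of percent); sterile hens die within 1–3 months with probability
  `sterility_mortality_coupling = 0.7`, always at least three weeks after
  laying stops. Deaths falling past the study window are censored.
* **Metabolites**: 693 features, log-normal, per-feature scales spanning
  four orders of magnitude. A fraction `frac_aging_features = 0.3` shifts
  its log-median monotonically with age by `aging_effect_size` baseline-SDs
  per 12 months (controls), attenuated by `molt_attenuation` post-molt. A
  fraction `frac_laying_features = 0.27` co-varies with the hen's *residual*
  fecundity — the deviation from the group-typical trajectory — at
  `laying_effect_size = 2` SDs per 0.1 of deviation, with the response
  saturating (`tanh`) so that a fully collapsed hen plateaus at about two
  SDs instead of scaling linearly off the chart; the default puts planted
  features' Spearman correlation with efficiency near 0.5. Residual (not
  raw) coupling is deliberate: raw fecundity declines with age, and coupling to
  it would hand every laying feature a monotone age trend, collapsing the
  two screens into one. Features planted in both sets get opposing signs so
  that higher efficiency always looks younger. Multiplicative noise follows
  the CV schedule: `cv_base = 0.25` at baseline, `+ cv_age_slope = 0.005`
  per month in controls, `− cv_molt_reduction = 0.05` after the molt.
* **Sampling**: 12 random living control hens per timepoint; a fixed molted
  subset chosen by excluding hens strictly above the 90th percentile of
  month-21 efficiency (ties kept — many hens tie at 100%) and drawing 12
  of the remainder, then tracked longitudinally. No molted samples exist at
  the 23-month validation timepoint.
* **Cytokines**: 9 log-normal channels declining with age in controls, the
  decline strongly attenuated in molted hens, 4 hens per group per
  timepoint.

**The default effect size.** `aging_effect_size` defaults to 2.5 SD per 12
months. This is a calibration, made once, to the screening procedure's
reported yield: at 12 hens per group and BH 0.1, a planted shift in the
1 SD/year range leaves the pairwise Mann–Whitney screen with per-pair power
near 0.5 and a step-up fixed point of only tens of features, which cannot
emulate a ~210-of-693 marker regime; at 2.5 SD/year the screen selects
roughly 200–220 features and recovers ~90% of the planted set. The value is
a parameter, and nothing in the package depends on the default beyond the
simulator's realism.

**What the simulator does not emulate.** LC–MS physics (retention times,
adducts, batch effects), missingness (an optional limit-of-detection
dropout exists but defaults to 0), serial correlation in daily laying
beyond the latent trajectory, seasonal effects, and the single dropped
control sample that made the motivating study's pooled cohort 47 rather
than 48. Passing recovery tests on simulated cohorts therefore demonstrates
that the *procedures* are implemented correctly and behave as designed under
the stated statistical structure — not that real plasma data will be as
clean. One structural consequence worth knowing: because age and efficiency
are confounded in any aging cohort, planted aging features unavoidably
correlate with pooled efficiency, so the laying screen's precision against
the planted set is structurally modest even when its sensitivity is high,
and the common-marker set is larger than a real study's would be.

## Numerical and reproducibility choices

* Permutation extremeness uses `>= observed − 1e-12`: "equal or bigger"
  with a guard against floating-point jitter in recomputed medians.
* Month lengths alternate 31/30 days; months are indexed by hen age (all
  hens share a hatching date, a single-flock design).
* Sterility is 21 consecutive zero-egg days while alive — three weeks at
  the finest resolution the log supports. Hens dying mid-month contribute
  to efficiency over the days they were alive; cohort medians count dead
  hens as zero producers so the statistic tracks the enrolled population.
* Mann–Whitney uses the exact distribution when the pooled sample is ≤ 14
  and tie-free, otherwise the normal approximation with tie and continuity
  corrections; fully tied input returns p = 1. Spearman uses the exact
  permutation distribution for n ≤ 10 and the t-approximation above (the
  pooled screens operate at n ≈ 48).
* Every stochastic step takes a seed; stage seeds are derived from the
  run seed by hashing, so adding a stage never perturbs another stage's
  stream. Two runs of `run_pipeline()` with the same config are
  byte-identical.
* Problem sizes in the test-suite: the structural tests run on 10-hen,
  80-feature cohorts over ages 21–27 with strengthened planted effects;
  recovery, noise and age-model properties are measured on the full
  693-feature design over 50 seeds; permutation calibration uses 500 null
  simulations at 200 permutations each. These sizes were chosen to give
  stable verdicts at interactive runtimes.

## Known limitations

* The forest span readout is conservative (see above); the package reports
  it as computed rather than rescaling it.
* The common-marker consistency filter is one operationalization of a
  qualitative criterion; both conditions can be toggled.
* The binomial survival comparison is ambiguous about which group supplies
  the null proportion; both conventions are implemented
  (`binomial_survival_test(..., null =)`) and neither is asserted as
  canonical.
* The simulator's mortality calibration targets the two arms' reported
  mortality regime only loosely; arm-level percentages fluctuate by several
  points across seeds at n = 32.
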