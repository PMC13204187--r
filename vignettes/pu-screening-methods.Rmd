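---
title: "Methods: positive-unlabeled screening for primary myelofibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positive-unlabeled screening for primary myelofibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfscreen)
```

## The problem

Primary myelofibrosis (PMF) is a rare myeloproliferative neoplasm
(population prevalence on the order of 0.06% even in enriched hospital
populations) whose early presentation — mild anemia, rising platelet
counts, nonspecific red-cell changes — hides inside routine complete blood
counts (CBC). An EHR screening model must therefore work under two linked
pathologies: extreme class imbalance, and *label incompleteness*. Hospital
records reliably encode confirmed diagnoses but almost never encode
rule-outs, so the "negative" class is really an unlabeled mixture of true
negatives and undiagnosed cases. This is the positive-unlabeled (PU)
setting: we observe `s` (labeled positive vs unlabeled), not `y`
(positive vs negative).

`pmfscreen` implements that screening analysis end to end: a synthetic PU
cohort generator, two-year analysis-window construction, longitudinal
feature engineering, class-balanced univariate statistics, two classical
PU wrappers (Elkan–Noto calibration and spy-based reliable-negative
mining) over pluggable base learners, and a repeated-cross-validation
evaluation framework built around non-interpolated average precision.

## The synthetic cohort generator

Real screening EHR data are private, so every downstream stage is
developed and tested against `generate_cohort()`, which emulates the
statistical structure the analysis assumes:

* **PU labels under SCAR.** A small set of labeled positives plus a large
  unlabeled pool containing latent positives drawn with probability
  `hidden_positive_rate`. Latent positives use the *case* distributions
  for labs, visits and codes but carry no diagnosis marker — labeled
  positives are thus Selected Completely At Random from all positives,
  which is exactly the assumption the Elkan–Noto estimator needs.
* **Class-conditional CBC marginals.** Each of the 22 CBC parameters is
  drawn from a log-normal family whose median equals the published
  per-class median (`cbc_parameter_specs()`), so e.g. platelets center at
  233 G/l in controls and 416 G/l in cases. The log-scale dispersion is
  set once from the published control range as `log(max/min)/6` (reading
  the extremes as roughly ±3 sigma). Percentage-type parameters are
  clipped to [0, 100]. Parameters marked "optional" (analyser-dependent
  indices such as RDW-CV, MPV, PDW) are dropped per measurement at rate
  0.3, producing the realistic missingness the prevalence filter exists
  for.
* **Visit process.** Visit counts are homogeneous Poisson over the
  two-year window at 1.5/year for controls and 2.5/year for cases,
  matching the published per-window visit medians (3 vs 5).
* **Diagnosis codes.** Each ICD-10 feature code is emitted at most once
  per window; for positives the emission odds are multiplied by a
  code-specific factor — 8 for the anemia code D64.8 and the
  observation-for-suspected-disease code Z03, near 1 for common
  primary-care codes.
* **Demographics.** Ages center at 63 (controls) vs 69 (cases), and the
  labeled positives carry their flagging ICD code and a Polish free-text
  diagnosis note on the anchor date itself, so the case-finding stage can
  rediscover them from the record alone.

The default configuration is desk-scale: one hundredth of the reference
population (1,100 unlabeled patients over 10 centers, 5 labeled positives
per center); `cohort_config_full_scale()` ships the 110,000-patient
configuration. The default `hidden_positive_rate` is 2%: the labeled-case
prevalence (0.061%) is *not* a latent-positive rate, and no published
value exists for one — at desk scale 2% keeps roughly 22 latent positives
in the pool, enough for the PU structure the methods target to be present
at all. Deliberately **not** modeled: within-patient temporal trends,
treatment effects, correlated multivariate lab structure, and
center-level batch effects. Passing tests on these cohorts therefore
demonstrate correctness of the machinery under the stated class-conditional
marginal structure, not clinical performance on real records.

## Windows, matching and leakage control

Case records are anchored at the diagnosis date; control anchors are
sampled uniformly between the first event and the last visit. The window
is the half-open interval `[anchor - 730 days, anchor)`: events on the
anchor day are excluded so same-day diagnostic labs cannot leak into
features. Records shorter than two years simply yield truncated windows.
Stratified control matching (`sample_matched_controls()`) uses age-decade
× gender strata with largest-remainder apportionment, bounding the
per-stratum frequency error by `1/n_total`. Before any code becomes a
feature, `exclude_leakage_codes()` removes the hematologic-malignancy
roots D45–D47, D70–D77 and C81–C96 by 3-character root comparison —
subcodes inherit their root's fate.

## Feature engineering

Each parameter's time-ordered measurements collapse to eight aggregates:
p25/p50/p75 (linear-interpolation percentiles), min, max, sample variance
(divisor n − 1, zero for singletons), absolute first-to-last difference,
and monotonicity (`last > first`; ties count as non-increase). The
aggregates are then discretized into 10 intervals whose interior edges are
the *control-group* deciles, anchoring every bin in the typical
physiological range of the large unlabeled population; a value equal to an
edge falls in the lower interval. Binned values replace the raw aggregates
in the model matrix (raw aggregates remain available to the univariate
module). Optional-parameter features, codes and phenotypes must be present
in at least 5% of both cohorts (inclusive) to survive; mandatory-CBC
aggregates and demographics are exempt. Missing stays missing — the `NA`
sentinel is passed through to learners, never imputed.

The schema arithmetic: 22 parameters × (1 measured indicator + 8
aggregates) + 5 phenotypes + 7 ICD-10 codes + age + gender = **212**
columns. The published component counts (22 + 176 + 5 + 7) sum to 210;
we resolve the two-column gap as the demographic pair and expose the
per-parameter count as a measured-within-window indicator.

A Weight-of-Evidence encoder (`woe_transform()`) is provided for learners
that need numeric categories:
`WoE(b) = ln(((pos_b + 0.5)/(pos_tot + 0.5k)) / ((neg_b + 0.5)/(neg_tot + 0.5k)))`
with pseudo-count 0.5 so empty cells stay finite, fitted on training rows
only. We do not assert any "zero-mean WoE" identity: the frequency-weighted
means of WoE are ±Kullback–Leibler divergences, which do not cancel in
general.

## Univariate statistics

Each feature is screened with a single-predictor logistic regression under
inverse-class-frequency weights (`n/(2·n_class)`), with Wald p-values from
the weighted information matrix (dispersion fixed at 1). For binary
predictors this weighting provably leaves the odds ratio at the 2×2
cross-product ratio — a property the test suite verifies against a
brute-force weighted-likelihood maximizer. Benjamini–Hochberg step-up
adjustment (via `stats::p.adjust`) controls the FDR over the *testable*
features only; zero-variance or single-class features are flagged and
excluded from the BH family rather than raising. The volcano table flags
features with `|log2(OR)| ≥ log2(1.5)` (0.585 at three decimals) and
adjusted p strictly below 0.05. `compare_partitions()` reuses the same
machinery for arbitrary binary partitions — most importantly false
positives vs true negatives among unlabeled patients.

## PU wrappers

Both wrappers operate over a `base_adapter` contract —
`fit(x, y, weights)` / `predict(fitted, x)` returning scores in [0, 1] and
accepting `NA` — with two shipped implementations: regularized boosted
trees (xgboost, shallow and few trees, native missing-value routing) and a
ridge logistic model on one-hot decile bins (glmnet). The logistic
fallback decile-bins continuous columns at fit time: a piecewise-constant
basis can represent the flat score plateaus PU calibration depends on,
which a single linear term cannot.

**Elkan–Noto.** Under SCAR, a classifier for `s` satisfies
`P(s=1|x) = c · P(y=1|x)` with `c` the labeling frequency. We hold out
10% of labeled positives (inside the training fold, never validation
data), fit the base learner on the remaining positives vs all unlabeled,
and estimate `c` as the mean holdout score, clipped to (1e-6, 1];
estimates at the floor raise an error because they signal an uninformative
learner. Calibrated predictions are `min(1, score/ĉ)` — weakly monotone,
strictly order-preserving below the cap. One deliberate exception to the
package-wide weighting policy: this base fit is **unweighted**. Balanced
class weights rescale the learned posterior in the positive region to
`w₁c/(w₁c + w₀(1−c))` — for a 5%-labeled cohort that pushes the holdout
mean toward 0.9 regardless of the true `c ≈ 0.5` — so weighting here would
break the very quantity the holdout estimates. Balance is restored
downstream by the calibration itself.

**Spy.** 10% of labeled positives (rounded up) are relabeled into the
unlabeled pool before the first-stage fit. Because spies are genuine
positives, their score distribution locates the positives; the threshold
`t` is the `⌈0.2·n_spies⌉`-th smallest spy score — our reading of a "20%
noise tolerance": up to 20% of spies may fall below `t`. Unlabeled records
scoring strictly below `t` become reliable negatives. The second stage
returns the spies to the positive set and refits on all labeled positives
vs reliable negatives only; the remaining ambiguous unlabeled records are
excluded from the refit and merely scored at prediction. Zero reliable
negatives is an error, never a silent fallback. Both spy stages keep
balanced weights (the threshold is an order statistic, unaffected by
monotone rescaling of scores).

## Evaluation

Model variants are compared under repeated randomized stratified 10-fold
cross-validation (default 10 repetitions → 100 validation runs). All
feature-engineering fits — bin edges, prevalence filters, WoE tables — and
all PU holdout/spy draws happen strictly inside training folds; a single
top-level seed fans out deterministically to per-fold substreams, so
identical configuration and seed reproduce every artifact byte for byte.

Metrics per run: average precision, AUROC (rank-based, midrank ties),
and precision/recall/specificity/F1 at a fixed 0.5 threshold on the
(calibrated) scores. AP is computed as
`Σ (R_n − R_{n−1}) · P_n` over descending score thresholds — a weighted
mean of precision with *no* interpolation, because trapezoidal area under
sparse precision-recall points materially overestimates performance at
this imbalance. Undefined ratios (0/0 precision when nothing is flagged)
are recorded as missing and excluded from summaries, with counts kept.
Run-level summaries report the median and the empirical 2.5th/97.5th
percentiles of the defined values; the percentile construction is our
choice, which is a comparability caveat against any interval built
differently. Recall-binned precision profiles pool the raw operating
points of all runs into 10% recall bins (median + IQR per bin); a
per-run-then-aggregate mode is available behind `profile_mode`.

Consensus classification assigns a patient TP/FP/FN/TN when one outcome
occurs in strictly more than half of their evaluations (exact ties are
`unstable`), and `venn_counts()` intersects those sets across model
variants. In a PU cohort the interesting set is the consensus FP: patients
persistently flagged against their unlabeled label. On synthetic cohorts
the latent-positive fraction inside the consensus-FP set exceeds the
background rate by an order of magnitude — the synthetic analogue of
finding undiagnosed cases among a screen's "errors". The screening
arithmetic helpers close the loop: `enrichment_factor()` (precision over
prevalence, both in percent) and `workload_estimate()` (15 minutes of
review per flagged patient).

In PU evaluation all threshold metrics treat unlabeled as negative, so
they are approximations; on cohorts with hidden positives the PU variants
typically trade precision for recall relative to the supervised baseline.
We report that direction but do not hard-assert it — it is a stochastic
tendency, not an invariant.

## Numerical conventions and problem sizes

All percentiles use linear interpolation between order statistics
(`quantile` type 7); variances are n − 1; bin assignment counts edges
strictly below the value; BH p-values are floored at the smallest positive
double before adjustment to absorb separation-driven underflow. These
conventions are frozen in one constants file.

Test and acceptance batteries run at deliberately modest sizes chosen as
the package's own desk-scale study conditions: calibration-recovery
simulations at n = 2,000 with labeling frequency 0.5 over 20 fixed seeds,
and end-to-end consensus analyses on the default 1,150-patient cohort with
2 repetitions of 10-fold CV per seed. The full-scale configuration is
shipped but not exercised by default.

## Known limitations

* The generator's class-conditional independence of lab parameters ignores
  the strong physiological correlations of a real CBC; discriminative
  performance on synthetic cohorts is therefore optimistic.
* Case-finding uses one literal word-boundary regex and five ICD codes; no
  free-text NLP.
* `ĉ` estimation inherits the variance of a small holdout (10% of an
  already small positive cohort); per-fold estimates in small studies are
  noisy, which mirrors the wide sensitivity intervals such calibration
  produces in practice.
* Patients are not de-duplicated across centers, and the suspected-case
  washout re-evaluation is consumed as final labels, not simulated.
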