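---
title: "Risk stratification of ground-glass nodules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk stratification of ground-glass nodules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggnrads)
```

## The problem

Pure ground-glass nodules (GGNs) found on chest CT are overwhelmingly
neoplastic in high-prevalence screening populations, yet the standard
Lung-RADS management scheme handles them poorly: almost all GGNs are under
30 mm and would sit in low categories for years of follow-up. Two
complementary signals can sharpen management. First, the relationship
between the nodule and its vessels (GVR type I pass-by, II pass-through,
III distorted/dilated, IV complicated) is strongly associated with
malignancy and drives a *complementary* Lung-RADS 1.1 category. Second, a
convolutional-network classifier emits a continuous malignancy-risk score
per nodule. `ggnrads` implements the combination of the two as a
deterministic decision rule, plus everything needed to evaluate it.

## The stratification model

Three strategies are computed for every nodule.

**Rule-only (complementary Lung-RADS 1.1).** From GVR type, diameter and
the radiologist's suspicious-findings flag:

| Category | Condition |
|---|---|
| 2 | type I and size < 30 mm |
| 3 | type I and size ≥ 30 mm; or type II, any size |
| 4A | type III, any size |
| 4B | type IV, any size |
| 4X | category 3/4A/4B with additional suspicious findings |

The categories are totally ordered, 2 < 3 < 4A < 4B < 4X. Exactly one rule
fires for every valid input (the test suite enumerates the partition
across the 30 mm boundary).

**Score-only.** The continuous malignancy score (percent scale) is binned
low `[0, 50)`, medium `[50, 70)`, high `[70, 100]`; a medium or high bin
is a positive call.

**Combined (score-based upgrade).** Categories 2 and 4X are managed on the
rule alone; categories 3, 4A and 4B are upgraded exactly one step (3→4A,
4A→4B, 4B→4X) when the bin is medium or high, and kept on a low bin. The
upgrade is monotone — the final category is never below the initial one —
so the combined strategy can only add positives relative to the rule.

All strategies binarize at the *neoplasm point*: final category ≥ 4A
predicts a neoplastic lesion.

### Numerical and boundary choices

* **Bin boundaries.** The published bin labels ("<50%", "50–70%",
  "70–100%") overlap at 50 and 70; the intervals here are half-open and
  lower-inclusive, which matches "<50%" exactly and resolves both
  overlaps the same way.
* **Size boundary.** Exactly 30 mm escalates a type-I nodule to
  category 3.
* **Flag timing.** The suspicious-findings flag is applied *before* the
  score combination (4X is an input row of the upgrade table), and it
  never escalates category 2. Whether the flag should be re-checked after
  an upgrade is unspecified in the source scheme; the engine deliberately
  applies it only pre-combination, so 4B + medium yields 4X through the
  upgrade path alone.
* **Operating point.** The published scheme defines its score threshold
  operationally (matching the radiologists' average sensitivity), which
  is not actionable without the underlying score distribution; the
  published low/medium/high bins are taken as *the* operating point.

## The metric panel

For one binary strategy on one split the confusion matrix (TP, FP, FN,
TN) yields: precision TP/(TP+FP); recall TP/(TP+FN); accuracy; Fβ =
(1+β²)PR/(β²P+R) with β = 1 for the per-class F1 and β = 0.5 for the
"weighted" F score (weighting precision over recall); the Matthews
correlation coefficient, identically the Pearson correlation of the 0/1
indicator vectors; and the single-operating-point ROC AUC, (sensitivity +
specificity)/2, which equals the Mann–Whitney probability with ties
counted half. Both identities are property-tested against independent
brute-force oracles (indicator-vector correlation; O(n²) pair counting)
on every matrix with total ≤ 12 and a thousand random larger ones.

Metrics are computed and stored as fractions; percent formatting (two
decimals, round half up) happens only at the report layer. A zero
denominator raises a typed `undefined_metric` condition rather than a
silent 0 or `NaN` — small synthetic cohorts legitimately produce empty
cells, and `metric_panel()` marks such fields `NA` instead of failing.

`printed_recall_variant()` (TP/(TP+TN)) exists only because published
tables sometimes follow that ratio in their "recall" row; it is not a
recall and is never used by default. `auc_ci_hanley_mcneil()` provides a
normal-approximation AUC interval; published intervals computed by other
(unstated) methods will generally not match it.

### The reference table and its printed anomalies

`reproduce_table4()` recomputes the panel from six embedded confusion
matrices (three strategies × training/validation) and audits every cell
against the published value at one unit in the last printed place (0.01
on two-decimal percents, 0.001 on AUC, 0.05 on the one-decimal recall
row). Most cells reproduce exactly. Five do not, and are flagged as
*known printed anomalies* rather than matched: the whole recall row
(follows TP/(TP+TN)); the training score-only F1 (printed 89.40, formula
gives 95.26); the training and validation score-only MCC (printed
15.64/2.73, formula gives 14.21/11.28); and the training score-only AUC
(printed 0.606, formula gives 0.608). The audit asserts that the
reproducible cells match and that the anomalous cells do *not* — a run in
which an anomalous cell suddenly "matched" would itself be a bug.

## The synthetic cohort generator

No per-nodule data are publicly deposited, so the pipeline is exercised
on synthetic cohorts drawn from a generative model with the reference
cohort's structure: per nodule, a truth label (prevalence 527/551), then
GVR type, suspicious flag and malignancy score conditional on truth, and
a truth-independent size; patients carry 1–3 nodules with probabilities
(467, 33, 6)/506 and are assigned whole to training with probability
205/506.

Calibration choices, made once from the published margins:

* **Size** (mm): normal with parent SD 6.58, truncated at 0.1 mm, with
  the location solved by `uniroot` so the *realized* mean is 13.96.
  Truth-independent by default because only a pooled mean ± SD is
  reported; conditional size effects can be configured.
* **GVR type.** Only pooled frequencies (47, 58, 64, 381) are published,
  no per-truth cross-tabulation, so any class-conditional split matching
  the margins is non-unique. The default fixes the expected
  non-neoplastic composition at (6.5, 6.5, 4, 7) — skewed toward types
  I/II — and obtains the neoplastic composition in closed form from the
  mixture identity, which puts the rule-only strategy's expected
  sensitivity/specificity near the published operating characteristics
  (≈ 0.83 / 0.54). This is one documented solution, not a claim about
  the real cohort. (The pooled type counts sum to 550 while the cohort
  has 551 observations — an inconsistency in the source table; the
  probabilities are normalized over their own total.)
* **Scores.** Beta distributions rescaled to [0, 100] — bounded support
  matches the percent scale and two parameters (mean, concentration)
  suffice — with means solved so that P(score ≥ 50 | neoplastic) =
  294/311 and P(score < 50 | non-neoplastic) = 3/17, at concentrations 6
  and 4 (unimodal, realistically spread shapes).
* **Flag**: probability 0.05 given neoplastic, 0 given non-neoplastic,
  so 4X inputs occur but rarely.
* **RNG**: one private stream per `generate_cohort()` call, seeded from
  the config; the caller's `.Random.seed` is saved and restored. Sizes
  and scores are rounded to two decimals, as such measurements are
  reported; the probability mass this moves across the 30 mm and 50 %
  boundaries is negligible at the simulation sizes used.

Because every strategy is a deterministic function of the generated
features, expected sensitivity, specificity and AUC have closed forms:
`expected_metrics()` enumerates the discrete cells (GVR type × flag) and
integrates the size and score densities over each rule region. It shares
no sampling code with the generator and serves as the independent oracle
for the Monte-Carlo recovery tests, which run at roughly 10⁴ nodules in
the unit suite and 10⁵ in the end-to-end suite (sizes chosen to make the
3-standard-error bands tight while the whole suite stays quick), agreeing
within 3 Monte-Carlo standard errors throughout.

**What passing these tests shows — and does not.** The generator draws
features independently given truth; real cohorts have correlated
features (large nodules tend to have complicated vasculature and high
scores), reader variability, and per-patient clustering beyond the
nodule count. Recovery of the closed form therefore validates the
pipeline's *correctness*, not the clinical performance of the rules on
real data; the embedded reference matrices are the only link to observed
performance.

## Data contract

Cohorts are CSV: UTF-8, header row, columns `patient_id, nodule_id,
gvr_type, size_mm, dl_score, suspicious_features, truth, split`; GVR
tokens `I`–`IV`, booleans `true`/`false`, categories serialized exactly
as `2, 3, 4A, 4B, 4X`. Scores live on the percent scale [0, 100]; a file
whose scores all lie in [0, 1] is rejected as fraction-scaled rather than
silently rescaled (a silent ×100 error is the worst failure mode here).
Missing values are errors, not imputed, so the rule engine is total on
any cohort that validates; validation reports every offending row with
its reason in one pass. Writing then reading a cohort is the identity on
the data model.

## Known limitations

* The score classifier itself is out of scope; scores are inputs
  (simulated or supplied), never computed from images.
* Single-operating-point AUC is the only AUC: the strategies are
  categorical, so no multi-threshold ROC exists.
* The Hanley–McNeil interval is a convenience, not a reproduction of any
  published interval.
* Calibration of the generator to published margins is non-unique; see
  above.

```{r example}
rep4 <- reproduce_table4()
all(rep4$agrees)

cfg <- default_config(n_patients = 500, seed = 7)
cohort <- generate_cohort(cfg)
summarize_cohort(cohort)
evaluate_predictions(stratify_cohort(cohort))
```
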