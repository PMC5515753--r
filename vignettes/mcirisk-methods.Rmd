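---
title: "Risk scoring for malignant cerebral infarction: models, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk scoring for malignant cerebral infarction: models, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcirisk)
```

## The clinical setting and the scores

Large hemispheric infarction (LHI) — ischemic stroke involving at least
half of the middle cerebral artery (MCA) territory — carries a high risk
of malignant edema and in-hospital death, and the decision window for
decompressive surgery is short. `mcirisk` implements an additive
three-score system built entirely from parameters available at or within
five days of admission, plus the statistics needed to evaluate such
scores on a cohort.

**Infarct classification.** The MCA territory is divided into deep,
superior, and posterior subdivisions. A *complete* MCA infarction (CMCA)
involves all three; this is a set condition, deliberately independent of
the estimated territory fraction, because a complete infarct is defined
by which territories are hit, not by a planimetric estimate. An
*incomplete* MCA infarction (IMCA) involves at least 50% of the
territory without covering all three subdivisions. Anything smaller is
below the LHI threshold (`NOT_LHI`); the mortality scores are undefined
there and `score_patients()` marks them `NA`.

**CHADS₂** is the standard cardioembolic-risk score: congestive heart
failure, hypertension, age ≥ 75, and diabetes score one point each, and
prior stroke or TIA two points (range 0–6). The hypertension component
uses the *history* flag, not admission blood pressure, following the
usual CHADS₂ convention. Used inside the mortality scores, CHADS₂ is
dichotomized at ≥ 4.

**CMCA score** (range 0–5, default positivity cutoff ≥ 2) adds one point
for each of: >1/3 early CT hypodensity, the hyperdense MCA sign, early
brain edema (sulcal effacement, mass effect, midline shift, or
ventricular compression), admission NIHSS ≥ 17, and stroke in
progression. *Stroke in progression* means a rise of ≥ 2 NIHSS points
between admission and day 5, or a stroke-related death. Note a temporal
caveat: the score contains a day-5 variable yet predicts a
classification itself made on second imaging within five days. The
package computes the score as defined and leaves the interpretation of
that circularity to the analyst; the score remains useful as a
descriptive severity index even where it cannot be a purely prospective
predictor.

**Mortality score 1** (range 0–2, cutoff ≥ 1) gives one point each for
CMCA and CHADS₂ ≥ 4. **Mortality score 2** (range 0–3, cutoff ≥ 2) adds
a third point for NIHSS ≥ 26 within the first five days.

### The NIHSS window for mortality score 2

The severity component of mortality score 2 can be read as "NIHSS ≥ 26
on day 5" or "NIHSS ≥ 26 during the first five days". The package
defaults to the second reading, implemented as the maximum of the
admission and day-5 values (`nihss_window = "first5"` in
`score_cutoffs()`): peak severity within the window is the clinically
conservative choice, since a patient who deteriorates past 26 and then
recedes — or dies before day 5 — plainly crossed the severity threshold.
The day-5-only reading is available as `nihss_window = "day5"`; with a
missing day-5 value it falls back to the admission NIHSS, because no
imputation model is assumed anywhere in the package.

### Missing day-5 assessments

A survivor without a day-5 NIHSS evaluates stroke-in-progression to
`FALSE` with a data-completeness warning, and contributes the admission
value as the five-day peak. The alternative — dropping the patient or
imputing — would either discard otherwise-complete records or invent a
trajectory; flagging the optimistic default was judged safer. A
stroke-related death forces stroke-in-progression `TRUE` regardless of
the day-5 value.

## Evaluation statistics

All of the evaluation machinery is implemented from first principles
(only the distribution functions `pchisq`, `dhyper`, `pt` come from base
R), and the test suite checks each piece against an independent oracle:
brute-force pairwise concordance for the AUC, an exhaustive threshold
scan for the Youden cutoff, full enumeration for the Fisher test, the
closed-form pooled formula for the t statistic, and base R's
`chisq.test`/`fisher.test`/`t.test` as cross-checks.

- **Prediction convention.** Positive means `score >= cutoff`,
  everywhere: every published cutoff for these scores is inclusive, and
  the ROC, `sens_spec()`, and the positivity flags all share the
  convention (a consistency test enforces it).
- **ROC and AUC.** One ROC point per distinct score value, plus the
  all-negative endpoint at an infinite threshold; AUC by trapezoidal
  integration, which on a step ROC equals the Mann–Whitney concordance
  probability with ties counted ½. Inputs with a single outcome class
  are a hard error at the statistic level and an explicit, noted
  omission at the pipeline level.
- **Cutoff selection.** "Best combination of sensitivity and
  specificity" is operationalized as Youden's J = sensitivity +
  specificity − 1, the standard choice when no loss function is given.
  Ties are broken toward higher sensitivity (missing a malignant course
  is costlier than a false alarm), then toward the lower threshold. J
  values that are mathematically equal can differ in the last floating-
  point ulp, so ties are detected with an absolute tolerance of 1e-9 —
  negligible against the J granularity of integer scores on realistic
  cohort sizes.
- **Chi-square without continuity correction.** The uncorrected Pearson
  form reproduces, from counts reconstructed out of printed per-group
  percentages (groups of 33 and 44), the published group-comparison
  p-values: stroke in progression 11/33 vs 6/44 → p = 0.039 (printed
  .04), brain edema 18/33 vs 13/44 → p = 0.027 (printed .03), HMCAS
  18/33 vs 11/44 → p = 0.0081 (printed .008), >1/3 hypodensity 16/33 vs
  7/44 → p = 0.0020 (printed .002). The Yates-corrected variant does not
  reproduce them and is offered only as a flag. One printed cell does
  not reproduce under either form: the mortality comparison (24.2% vs
  2.3%, printed P = .03) gives p ≈ .003 uncorrected and ≈ .004 by Fisher
  on the reconstructed counts 8/33 vs 1/44; the test behind that printed
  value is unclear, so the package simply reports both tests.
- **Fisher exact test.** Two-sided p by summing hypergeometric
  probabilities of all tables with the observed margins that are no more
  probable than the observed table, with the conventional 1e-7 relative
  tolerance for floating-point ties.
- **t test.** Pooled-variance Student form by default (the group
  comparisons were reported as plain two-sample t tests); Welch behind
  `var_equal = FALSE`. Zero pooled variance with equal means returns
  statistic 0, p = 1; with unequal means an infinite statistic, p = 0.
- **Percentages.** `pct()` rounds half-up, matching the one-decimal
  reporting convention of clinical tables (42.857 → 42.9). Raw p-values
  are always emitted alongside any journal-style string.

## The synthetic cohort generator

`simulate_cohort()` exists so that scoring and evaluation can be
exercised end to end without the study's raw per-patient data, which
were never deposited. Its defaults *are* the published marginal
structure of the 77-patient cohort, and they are treated as fixed study
conditions, not tuning knobs:

| Parameter | Default | Source |
|---|---|---|
| `n` | 77 | cohort size |
| `p_cmca` | 0.429 | 33/77 complete infarctions |
| HMCAS prevalence | 0.5455 / 0.25 | printed CMCA / IMCA percentages |
| brain edema prevalence | 0.5455 / 0.2955 | printed |
| >1/3 hypodensity | 0.488 / 0.159 | printed (see note below) |
| admission NIHSS mean | 20.3 / 15.6 | printed group means |
| day-5 NIHSS mean | 20.8 / 14.6 | printed group means |
| age | N(70.7, 12.6²), clipped to [40, 94] | printed mean ± SD and range |
| hypertension | 0.688 | printed overall prevalence |
| overall mortality | ≈ 0.117 | calibrated, see below |

The printed hypodensity prevalences are internally inconsistent: 48.8%
of 33 is not an integer (16/33 = 48.5%), while 15.9% of 44 is exactly 7.
The generator keeps the printed proportions as given; the reconstructed
count used in the chi-square check is 16/33.

Where the publication prints nothing, one value was fixed as clinically
plausible for an elderly LHI cohort and not revisited: NIHSS standard
deviations 5.0 per group (only the means are reported), day-5 increment
SD 3.0, male fraction 41/77, and risk-factor prevalences (CHF 0.15,
diabetes 0.35, prior stroke/TIA 0.20, atrial fibrillation 0.40, smoking
0.35, hypercholesterolemia 0.30, coronary disease 0.20, thrombolysis
0.15) shared by both groups, since the groups did not differ
significantly on any of them. Craniectomy is 9% in the CMCA group and 0
in IMCA, mirroring the reported 3/33 vs 0/44.

**Mechanics.** Group membership is Bernoulli(0.429). CMCA patients get
all three territories and a fraction in [0.85, 1]; IMCA patients two
territories and a fraction uniform in [0.5, 0.95]. Binary fields are
conditionally independent given group — only marginals are published, so
no correlation structure is assumed. NIHSS values are rounded, clipped
normals; the day-5 value is generated as admission plus a group-specific
increment whose mean hits the day-5 target (+0.5 for CMCA, −1.0 for
IMCA), so stroke-in-progression arises organically from the trajectory
rather than being drawn directly.

**Mortality model.** Death is Bernoulli with
`plogis(a + 1.5 × MS2)`, where MS2 is the patient's mortality-score-2
total. A logistic link in the score total is the minimal generative
choice that makes the score genuinely prognostic in the synthetic data
(the study asserts the association but fits no model). The slope of 1.5
per point gives a strong but not deterministic gradient (≈ 3%, 12%, 38%,
73% mortality at totals 0–3); the intercept a = −3.50 was calibrated
once, by solving E[plogis(a + 1.5·MS2)] = 0.117 under the default
parameters at large n, and then frozen. 90% of deaths are marked
stroke-related.

**What the generator does not emulate** — and hence what passing tests
do and do not show about real data: no correlations among risk factors
or CT signs within a group (real comorbidities cluster), no
deterioration-then-death trajectories (death is a function of the score
total, not of the day-5 path), no missing-data mechanism by default, no
treatment effects (thrombolysis and craniectomy are passthrough flags),
and no attempt to reproduce the nine individual published decedents,
whose full field values are not printed. Calibration tests therefore
demonstrate that the *pipeline* recovers what the generator put in — not
that the scores would achieve the published AUCs on a real cohort, which
cannot be checked without the undeposited raw data. For the same reason
the published cohort-level AUCs (0.95, 0.87, 0.79) and operating points
are not test targets; the suite instead verifies the machinery by
exhaustive and property-based oracles.

## Problem sizes in the test suite

Exhaustive checks enumerate all component combinations of every score
(2⁵ for CHADS₂ and the CMCA score, 2³ for the mortality scores) and all
2×2 tables with total ≤ 40 for the Fisher test (132,460 tables). Monte
Carlo checks use 200 random ROC inputs of size ≤ 30; generator
calibration uses single cohorts of n = 10,000 (marginals, ± 0.02 on
prevalences, ± 0.5 on NIHSS means) and n = 20,000 (parameter recovery),
1,000 replicate cohorts of n = 77 for the mortality count (median deaths
in [7, 12], bracketing the observed 9), and n = 5,000 for the
score–mortality coupling. These sizes keep every sampling check several
standard errors inside its tolerance while the whole suite stays fast.

## Known limitations

- The scores were derived on a single-center cohort of 77; the package
  evaluates them but cannot externally validate them.
- The CMCA score's progression component limits its use as a purely
  admission-time predictor (see the circularity note above).
- `NOT_LHI` patients are carried through scoring with explicit `NA`
  mortality scores but are excluded from the group-comparison and ROC
  sections, which are defined on LHI patients.
- The generator's conditional-independence assumption makes synthetic
  AUCs systematically different from the published ones; they are
  reported by the acceptance script as the package's own computed
  quantities, not as reproductions.
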