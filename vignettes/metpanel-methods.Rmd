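---
title: "Methods: evaluating the plasma metanephrine triplet panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating the plasma metanephrine triplet panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metpanel)
```

## The screening problem

Pheochromocytomas and paragangliomas (PPGLs) are catecholamine-producing
tumors; head-and-neck paragangliomas (HNPGLs) are their typically
low-secreting counterparts. Biochemical screening measures the plasma
O-methylated metabolites normetanephrine (NMN, from norepinephrine),
metanephrine (MN, from epinephrine) and methoxytyramine (MTY, from
dopamine). `metpanel` implements the evaluation machinery for this triplet
panel: cutoffs, classification, cohort performance, and
likelihood-ratio-based predictive-value curves, together with a calibrated
synthetic cohort generator so that the entire pipeline is testable without
patient-level data (which the underlying studies do not publish).

## Cutoffs

A result is **positive when the concentration is equal to or above its
upper cutoff (UC)**. MN and MTY use fixed cutoffs (0.45 and 0.10 nmol/L;
the MTY cutoff corresponds to the maximum observed in a tumor-free
reference population, and `derive_uc()` also offers 97.5th/99.5th
percentile estimators using linear interpolation between order statistics,
R's default quantile definition — fixed so derived cutoffs are
reproducible). NMN rises with age; its cutoff is cubic in age,

$$\mathrm{UC}(a) = 2.074\times10^{-6}\,a^3 + 0.54 \ \text{nmol/L},$$

evaluated at age 5 for younger children (the fit's validity floor) and
capped at 1.09 nmol/L. Three conventions deserve note, because the
published description leaves them open:

* **Cap semantics.** The raw cubic slightly exceeds the printed cap at 65
  years (≈1.11 vs 1.09 nmol/L), so the cutoff is implemented as
  `min(formula, cap)`; we assume the cap holds at all older ages.
* **Unrounded comparisons.** Positivity is always decided against the
  unrounded cutoff; two-decimal values (0.54, 0.55, 1.09) are display
  conventions.
* **Dual units.** The pg/mL parameterisation
  ($3.792\times10^{-4} a^3 + 98.9$, cap 200) was fitted and rounded
  independently of the nmol/L one, so the two curves agree only to within
  about 2% after molar-mass conversion; both are carried in
  `cutoff_policy()`. Molar masses are free-base values (NMN 183.2,
  MN 197.2, MTY 167.2 g/mol), which reproduce all published pg/mL ↔ nmol/L
  cutoff pairs under two-decimal rounding. The canonical internal unit is
  nmol/L; pg/mL is converted at the I/O boundary only.

## Classification

`classify_cohort()` produces per-metabolite flags, fold-elevations
(value / cutoff), and the mutually exclusive **combination category**
(none, three singles, three pairs, triplet) that drives the
predictive-value analysis. A *strong positive* is any fold strictly
greater than 2 — the "more than 2-fold" rule is strict, so a fold of
exactly 2.0 does not qualify, whereas a value exactly at the cutoff
(fold 1.0) is positive. Missing concentrations can never be positive; the
row is marked incomplete. The MN+MTY-without-NMN category is representable
even though secreting tumors essentially never produce it — the simulator
uses it as a calibration check.

## Cohort performance

`evaluate_rule()` scores a subject positive when any metabolite of the
rule subset is flagged, and reports sensitivity and specificity as
percentages (one-decimal display rounding). Paired rules on the same
subjects are compared with the **exact McNemar binomial test** on
discordant pairs (the published table marks significance without naming a
test; the exact test is the conservative choice at these discordant
counts). ROC analysis uses the rank-based (Mann–Whitney) AUC with ties
counted 1/2, and paired AUC differences use DeLong's covariance estimator
(delegated to the pROC package); the original analysis names neither its
AUC comparison nor its transform, so `fit_panel_score()` fixes a
documented choice: logistic regression on log cutoff-normalised
concentrations, $\log(\text{value}/\mathrm{UC}(\text{age}))$, which makes
the score age-consistent, with zero or missing values floored at half the
smallest positive observation before the log.

## Predictive value

All internal probability arithmetic is in fractions; percentages appear
only at I/O. The positive likelihood ratio is sensitivity divided by the
false-positive rate, and posttest probability follows odds-form Bayes:

$$P = \frac{o\,LR^+}{1 + o\,LR^+},\qquad o = \frac{p}{1-p}.$$

Quoted percentages use half-up rounding (`round_half_up()`), under which
the published paired-positive inputs (sensitivity 49.3%, false-positive
rate 0.18%) reproduce the published 58%→94% posttest span over pretest
prevalences of 0.5–5%. The published 9–57% span for single-positive
results is *not* pinned as a target: no single sensitivity/false-positive
input pair reproduces both endpoints under one rounding convention, so the
computation is exposed but that figure is not asserted.

## Reference-population statistics

`stratified_summary()` reports median (min–max) per metabolite for the
conventional strata (all, sex, decade age bands, blood-pressure status).
Age bands are right-open decade bins so fractional ages partition cleanly;
the even-*n* median is the midpoint of the central order statistics.
Adjusted group effects (`adjusted_group_difference()`) come from linear
models on log concentration with additive age/sex terms, reported as
$100(e^{\beta}-1)$ percent differences — the form in which effects such as
"12% higher NMN in hypertensives" are quoted. Age correlations are Pearson
on log concentration; the published estimator and scale are unstated, so
this is a documented assumption tested only against a band (0.2–0.45
around the published r = 0.321).

## The synthetic cohort generator

The generator defines the study conditions under which the package is
tested. It emulates four groups with published aggregate characteristics:

* **Reference** (n = 423, ages 18–81 uniform — only medians and ranges are
  published, so ages are uniform over the printed range; 44% male, 62%
  hypertensive). Concentrations are log-normal. MN and MTY have fixed
  locations (female medians 0.135 and 0.027 nmol/L) with male
  multipliers ×1.30 and ×1.09; NMN carries a hypertension multiplier
  ×1.12 and an age trend.
* **NMN age model.** The published facts are in tension: the cutoff curve
  doubles between ages 5 and 65 (it tracks the 97.5th percentile), yet the
  observed age correlation of NMN is only ≈0.32 and the reference range
  tops out near 1.06 nmol/L. A pure location trend that tracks the cutoff
  forces r ≈ 0.5. The model therefore combines a gentle location slope
  (0.008 per year on the log scale) with **age-increasing dispersion**
  chosen at every age so the population 97.5th percentile equals the
  capped cubic cutoff. By construction ~2.5% of tumor-free subjects exceed
  the age-specific cutoff at every age, while the median (0.34 nmol/L) and
  the age correlation (0.32) match the published values simultaneously.
* **No-tumor screening population** (n = 1712, ages 10–93). Same law, plus
  an independent per-metabolite tail replacement that lifts a value just
  above its cutoff with small probability, calibrated once so the
  false-positive rates are ≈3.9% (NMN), 0.4% (MN) and 1.1% (MTY). Because
  replacements are independent, multi-positive false positives are rare
  (≈0.07%), slightly rarer than the published 0.06–0.29% pair rates;
  specificity of the panel rules is reproduced within half a percentage
  point. Setting the replacement probabilities to zero reverts to the
  reference calibration.
* **Tumor cohorts.** Each tumor draws its combination category from a
  phenotype mixture, then elevated metabolites are set to cutoff × fold
  with log-normal folds truncated to fold > 1 (most tumors well above
  2-fold, some borderline), and non-elevated metabolites are drawn from
  the tumor-free law truncated below the cutoff. The PPGL mixture is the
  published category table itself (counts 47/9/3/56/46/0/49 positive
  categories plus 3 silent out of 213), so panel sensitivities
  (97.2%/98.6%), the 70.9% multi-positive share and the category split are
  matched by construction; fold distributions were tuned once (see
  `scripts/calibrate_simulator.R`) so that ~86.9% of tumors show a
  more-than-2-fold elevation. The HNPGL mixture (half silent, no MN
  secretors) targets the printed 22.1%/50.0% sensitivities; the published
  counts (8/38 = 21.1%) and printed percentage (22.1%) disagree slightly,
  and the mixture follows the printed percentages of the performance
  table.

All randomness flows from one master seed with fixed per-group offsets,
so each group's cohort is individually reproducible and groups are
mutually independent.

**What the generator does not emulate:** assay noise, diurnal/dietary and
medication effects, sampling-posture differences, correlated false
positives (borderline patients elevated in several metabolites at once),
genotype–phenotype coupling, and any within-subject repeat-measurement
structure. Passing tests therefore demonstrate that the *evaluation
machinery* is correct under the published aggregate conditions, not that
the generator reproduces individual-level biology.

## Numerical choices and problem sizes

Degenerate inputs are rejected with structured errors (empty cohorts,
single-class AUC, zero-discordance McNemar returns p = 1, sensitivity
undefined without diseased subjects). Truncated draws use inverse-CDF
sampling, so no rejection loops. Test problem sizes: distributional
checks run at 20,000–40,000 subjects where a tight check on a simulated
rate is needed and at the published group sizes (213/38/1712) for
cohort-level reproduction, with 20 fixed seeds for the
coverage check of the published sensitivities/specificities and one
50,000-per-group run for the large-sample check; these sizes keep rate
standard errors near or below 0.2 percentage points.

## Known limitations

* The published AUCs (0.984/0.991 for PPGLs, 0.627/0.801 for HNPGLs),
  reference medians and correlation coefficients depend on unpublished
  per-patient data; the package asserts calibration bands and qualitative
  orderings (for example, adding MTY increases the HNPGL AUC) rather than
  those exact values.
* Tumor concentration distributions are artifact choices validated only
  against published aggregate proportions.
* Lower reference limits and between-assay transference statistics are out
  of scope.
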