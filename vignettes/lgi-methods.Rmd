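---
title: "Methods: the LGI score pipeline and its synthetic validation cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the LGI score pipeline and its synthetic validation cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgiscore)
```

## The low-grade inflammation score

The LGI score is a composite marker of chronic low-grade inflammation built
from four quantities available on any routine admission blood panel:
C-reactive protein (CRP, mg/L), the leukocyte count (WBC, 10^9/L), the
platelet count (PLT, 10^9/L) and the neutrophil-to-lymphocyte ratio
(NLR = neutrophils / lymphocytes). Each marker is ranked within the analyzed
cohort and divided into deciles; deciles 1–4 score −4 to −1, deciles 5 and 6
score 0, and deciles 7–10 score 1 to 4. The LGI score is the sum of the four
marker scores and therefore ranges from −16 (all four markers in the bottom
decile) to 16 (all four in the top decile). Higher scores indicate more
intense low-grade inflammation; all four markers are scored in the same
direction.

Two decisions here are genuinely open and we fixed them as follows.

* **Decile rule.** "Divided into 10 quantiles" does not pin down a quantile
  algorithm, and ties in counts are common. We use the mid-rank rule:
  observation *i* gets decile `ceiling(10 * r_i / n)` where `r_i` is its
  average (mid) rank. This is deterministic under ties (tied values always
  share a decile), invariant to monotone transformations, and reduces to the
  obvious assignment for distinct values. A cohort of 50 identical values
  lands entirely in decile 6 (mid-rank 25.5, `ceiling(5.1)` = 6).
* **Reference population.** Deciles are cohort-internal — computed on the
  sample being analyzed, not on external reference ranges. Quartile groups of
  the total score use the same mid-rank rule at the 25/50/75 percentiles, and
  the realized cut points are reported so tables can be headed
  "Q1 (≤ −5)" style.

Records whose lymphocyte count is not strictly positive cannot form the NLR;
they are excluded from scoring with a warning listing their ids
(complete-case behaviour), and the pipeline log accounts for every excluded
row.

## Endpoints

* Severe stroke: NIHSS > 5, applied at baseline and at day 7.
* Early neurological deterioration (END): day-7 NIHSS minus baseline
  NIHSS ≥ 2.
* 90-day outcome: excellent = mRS 0–1, poor = mRS 2–6 (death, mRS 6, is
  poor).
* Threshold-defined risk factors: hypertension is SBP ≥ 140 mmHg, DBP ≥ 90
  mmHg or antihypertensive use; diabetes is fasting glucose > 7.0 mmol/L or
  antidiabetic use; dyslipidemia is TC > 5.18 mmol/L or TG > 1.7 mmol/L.
  A single fasting glucose stands in for the "two or more measurements"
  clinical criterion because the schema carries one value per patient; this
  is a documented deviation.

## Association models

Quartile logistic models regress each binary endpoint on LGI quartile
indicators (reference Q1), at three adjustment tiers: crude; model 1
(gender, age); model 2 (model 1 + smoking, drinking, prior stroke, atrial
fibrillation, coronary heart disease, hypertension, diabetes, dyslipidemia).
For the 90-day outcome, model 2 additionally includes baseline NIHSS; for
the severity endpoints it deliberately does not, since NIHSS is the scale
those endpoints are defined on. Odds ratios are `exp(coef)` with Wald 95%
intervals `exp(coef ± 1.96·SE)` — the convention of the tables this mirrors.
The *p* for trend enters the quartile index as a single ordinal covariate
(1–4) and reports its Wald p-value: a one-degree-of-freedom monotone
dose-response test, chosen to stay inside the same regression framework.
Models are complete-case with the per-model *n* and dropped-row count
reported; separation or non-convergence raises a flag on the report rather
than failing silently or falling back.

Stratified analyses refit the crude quartile model within each level of
eleven stratifiers (baseline NIHSS ≤5/>5, gender, age <65/≥65, smoking,
drinking, prior stroke, heart disease, AF, hypertension, diabetes,
dyslipidemia). Effect modification is tested with a one-degree-of-freedom
likelihood-ratio test comparing pooled models with and without a
stratifier × ordinal-quartile interaction — a single *p* per stratifier,
matching the report format being reproduced. Whether the original stratified
estimates were crude or partially adjusted is not stated; crude is the
default, with the tier exposed as an argument.

## Discrimination: AUC, continuous NRI, IDI

These statistics are the analytical core and are implemented from their
definitions rather than delegated (an independent implementation, pROC,
is used only to cross-check the AUC and its DeLong interval in the test
suite).

* **AUC** is the Mann–Whitney concordance probability over all
  event × nonevent pairs with ties counted 1/2; its CI uses the DeLong
  variance computed from placement values.
* **Continuous NRI** = [P(up | event) − P(down | event)] +
  [P(down | nonevent) − P(up | nonevent)], where up/down compare the new
  model's predicted risk with the old model's and exact ties move neither
  way (an explicit, testable choice). Inference is the asymptotic normal
  test on the two net proportions.
* **IDI** is the change in discrimination slope,
  [mean(p_new|event) − mean(p_new|nonevent)] − [same for p_old], with an
  asymptotic two-sample test on the per-subject risk differences.

`compare_models()` fits the conventional prognostic model (age + baseline
NIHSS) and the add-on model (+ LGI score), both in-sample, and reports both
AUCs, the C-statistic difference, NRI and IDI. The LGI score enters the
add-on model as a continuous covariate by default; a quartile-coded variant
is available (`lgi_as_quartile = TRUE`) because the source analysis does not
state its coding. Performance is apparent (in-sample), matching the analysis
being reproduced — no cross-validation is applied by default. The raw LGI
score's own ROC is reported directly (a univariable logistic fit would give
the same AUC, since the fit is monotone in the score).

## The synthetic cohort generator

No patient-level data are deposited for this design, so the generator is a
first-class, tested module that emulates the *structure* of such a registry
cohort: marginal demographics and risk-factor prevalences taken from the
published baseline table (n = 876, 58% male, median age 70 [60.5, 78],
hypertension 69.2%, …), TOAST subtype proportions 35.4/13.7/40.9/10%, and a
baseline NIHSS that is negative binomial (size 1.3, mean 2.6) reproducing
the published median of 2 [1, 4].

The link between biomarkers and outcomes is a single latent standard-normal
inflammation factor per patient: it loads on each log-biomarker (defaults
0.80 CRP, 0.15 WBC, 0.25 neutrophils, −0.15 lymphocytes, 0.05 platelets —
acute inflammation raises CRP and granulocytes and depresses lymphocytes,
sharpening the NLR) and enters the logistic links for END (intercept
logit 0.08, slope 0.5) and the poor 90-day outcome (intercept −2.0, slope
0.6, plus 0.04 per year of age and 0.25 per baseline NIHSS point), and the
NIHSS log-mean (0.35). The published study describes no generative model;
this latent-factor construction is the package's own choice, the minimal
structure that makes the score–outcome association tunable and recoverable.
Setting every loading and latent coefficient to zero yields an exact null
cohort, which the test suite uses for coverage and uniformity checks. The
poor-outcome intercept −2.0 was chosen to match the published event
proportion (231/876 ≈ 26%); the defaults produce ≈ 25%.

Biomarker location/scale defaults are population-plausible rather than
paper-anchored, because the source reports no CRP/WBC/PLT summaries.
Neutrophil noise is correlated 0.7 with leukocyte noise (neutrophils are the
dominant leukocyte fraction), so physiologically impossible neut > WBC
panels are rare (~2%); they are flagged on read, never rejected, because
real panels occasionally contain them. Day-7 NIHSS is the baseline plus an
integer perturbation: when the END link fires the rise is ≥ 2 (2 plus a
Poisson excess), otherwise the change is capped below +2. mRS at 90 days is
drawn consistently with the dichotomous outcome (0–1 vs 2–6). All
randomness flows from one seeded private stream; the caller's RNG state is
untouched and a given config is byte-reproducible.

What the generator does **not** emulate: within-patient biomarker
measurement error or repeat measures, informative missingness (only
complete records are generated), treatment effects (thrombolysis and
endovascular patients are excluded from the target design), secular trends,
or any real biological correlation structure beyond the single factor.
Passing tests therefore demonstrate that the pipeline's statistics are
correct and recover known effects under the stated model — not that the
published registry estimates themselves are reproduced. The published
headline values (Q4 OR, AUC 0.682, NRI 18.7%, IDI 1.34%) depend on the
non-deposited registry and serve only as shape references for the reports.

## Descriptive tables and sample size

`build_descriptive_table()` mirrors clinical "Table 1" conventions.
Categorical variables use the chi-square test, switching to Fisher's exact
test whenever any expected cell is below 5 (the conventional gate; the
source names both tests but no rule). Continuous variables are gated per
variable: Lilliefors-corrected Kolmogorov–Smirnov normality within every
group and Levene's equal-variance test, both at α = 0.05, select
ANOVA/t-test with mean ± SD display versus Kruskal–Wallis/Mann–Whitney with
median [IQR]. The gate granularity (per variable, tested in every group) is
a documented choice; the test used for each row is recorded in the output.

`epv_sample_size(n_factors, epv, event_proportion)` implements the
events-per-variable rule `n_factors × epv / event_proportion`: with 15
factors, EPV 10 and event proportion 0.8 the requirement is 187.5; with
EPV 20 it is 375.

## Numerical and degenerate-input choices

* Deciles need n ≥ 10, quartiles n ≥ 4; smaller inputs abort with a clear
  error (the pipeline stage names itself in the message).
* A degenerate score distribution (all equal) yields a single quartile
  group with a warning rather than an arbitrary split.
* Constant vectors make the Spearman correlation undefined: `NA` with a
  warning, not an error.
* Perfect separation in a logistic fit sets a `separation` flag on the
  report (detected via the glm warning, non-convergence, |coef| > 15 or
  SE > 100).
* Predicted risks entering NRI/IDI must lie strictly in (0, 1).
* AUC confidence limits are truncated to [0, 1].

## Problem sizes used in validation

The simulation-based checks run 500 replicates of n = 800 cohorts for CI
coverage of known quartile log-odds ratios (accepting pooled coverage in
[0.93, 0.97]) and 500 null replicates each for the uniformity of the
p-for-trend and interaction p-values (Kolmogorov–Smirnov at α = 0.01).
These sizes give the uniformity and coverage tests enough resolution to
catch a miscalibrated Wald interval or test statistic while keeping the
default suite fast; they are the package's chosen validation conditions,
stated here so they can be scaled up by anyone wanting tighter Monte Carlo
error.
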