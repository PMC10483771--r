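# lgiscore

Low-grade inflammation (LGI) score analysis for acute ischemic stroke
cohorts.

Chronic low-grade inflammation is implicated in the progression and
outcome of ischemic stroke, and all of its routine blood markers — CRP,
the leukocyte count (WBC), the platelet count (PLT) and the
neutrophil-to-lymphocyte ratio (NLR) — are available from the admission
blood panel of every stroke patient. The LGI score combines them into one
composite: each marker is divided into cohort-internal deciles by the
mid-rank rule, decile *d* maps to a score

> deciles 1–4 → −4 … −1,  deciles 5–6 → 0,  deciles 7–10 → 1 … 4,

and the LGI score is the sum over the four markers, ranging from −16 to 16
with higher values indicating more intense inflammation.

The package is for biostatisticians and stroke researchers who want this
analysis as a tested, reusable pipeline rather than a one-off script. It
provides:

* **Scoring** — `compute_nlr()`, `assign_deciles()`, `decile_to_score()`,
  `compute_lgi_scores()`, `quartile_groups()`.
* **Endpoints** — stroke severity (NIHSS > 5 at baseline and day 7), early
  neurological deterioration (END: NIHSS rise ≥ 2 within 7 days), the
  90-day excellent/poor dichotomy (mRS 0–1 vs 2–6), and threshold-defined
  vascular risk factors.
* **Association models** — quartile logistic regressions (OR, Wald 95% CI)
  at three adjustment tiers, ordinal p-for-trend, Spearman correlation with
  NIHSS, stratified analyses with likelihood-ratio interaction tests.
* **Added predictive value** — ROC/AUC with DeLong confidence intervals,
  the continuous net reclassification improvement (NRI) and the integrated
  discrimination improvement (IDI), comparing a conventional prognostic
  model (age + baseline NIHSS) with the LGI add-on model. These statistics
  are implemented from their definitions, not delegated.
* **Synthetic cohorts** — `simulate_cohort()` generates seeded,
  byte-reproducible registry-like cohorts in which a latent inflammation
  factor links the biomarkers to the outcomes with known effect sizes, so
  every stage is testable against ground truth. Defaults mirror the
  marginal structure of an 876-patient registry (58% male, median age 70,
  hypertension 69.2%, poor 90-day outcome ≈ 26%, …).
* **Reporting** — descriptive "Table 1" builder with normality-gated test
  selection, the events-per-variable sample-size rule, and
  `run_pipeline()`, which writes the full report bundle (scored CSV,
  descriptive table, model JSON, stratified JSON, discrimination JSON, ROC
  coordinates, log with row accounting).

A thin command line lives at `exec/lgiscore`
(`simulate` / `score` / `run` subcommands).

## Worked example

```r
library(lgiscore)

cohort <- simulate_cohort(cohort_config(n_patients = 876, seed = 42))
scores <- compute_lgi_scores(cohort)
cohort$lgi_score    <- scores$lgi_score
cohort$lgi_quartile <- scores$lgi_quartile
cohort <- add_endpoints(cohort)

attr(scores, "quartile_cuts")
#> [1] -5  0  4

spearman_lgi_nihss(cohort$lgi_score, cohort$nihss_baseline)$rho
#> [1] 0.1874284

fit_quartile_logistic(cohort, "poor_90d", "model2")
#> Quartile logistic model: poor_90d (model2)
#>   n = 876 (0 dropped)
#>   Q1: reference (n=243, events=38)
#>   Q2: OR 1.44 (0.87, 2.38)  n=207 events=45
#>   Q3: OR 2.19 (1.34, 3.59)  n=187 events=62
#>   Q4: OR 1.86 (1.16, 2.98)  n=239 events=73
#>   p for trend: 0.004251

compare_models(cohort)
#> Added predictive value of the LGI score for 'poor_90d' (n = 876)
#>   AUC, LGI score alone:   0.605 (0.563-0.647)
#>   AUC, conventional:      0.691 (0.650-0.732)
#>   AUC, add-on:            0.705 (0.664-0.746)
#>   delta C-statistic:      0.0142
#>   continuous NRI:         27.5% (p = 0.000383)
#>   IDI:                    1.29% (p = 0.00103)
```

Reading the output: the quartile cut points say Q1 is LGI ≤ −5 and Q4 is
LGI > 4; patients in the top score quartile have about twice the adjusted
odds of a poor 90-day outcome relative to the bottom quartile, with a
significant monotone trend; and adding the score to the conventional
age + NIHSS model raises the C-statistic by 0.014 with significant
reclassification improvement (NRI 27.5%, IDI 1.29%). The sample-size
utility reproduces the design calculation `epv_sample_size(15, 10, 0.8)`
= 187.5.

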