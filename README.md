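# rivlmm

Predicting longitudinal visual-acuity (VA) response to intravitreal
anti-VEGF therapy, and ranking the candidate predictors by relative
importance.

Patients with neovascular age-related macular degeneration are followed
over two years of anti-VEGF treatment; their VA (ETDRS letters) is
measured at baseline and at 3, 6, 12 and 24 months, alongside clinical,
imaging (OCT), demographic and lifestyle variables — many of them
incomplete. `rivlmm` provides the full analysis pipeline for such
cohorts:

* **Linear mixed model** — for subject *i*,
  `Y_i = X_i β + Z_i u_i + ε_i`, with a correlated per-subject random
  intercept and time slope, `(time_weeks | subject_id)`; all fits by
  maximum likelihood (`lme4`), so models are comparable by
  `AIC = −2 logL + 2K` and `BIC = −2 logL + K log n`.
* **Exhaustive all-subsets search** over the candidate predictors
  (2^k models including the null; the full 19-candidate space is 524,288
  models), per imputed dataset.
* **Akaike-weight variable importance (RIV)** — per model,
  `w_i = exp(−Δ_i/2) / Σ_r exp(−Δ_r/2)`; per variable, the inclusion sum
  `w+_j = Σ_{i: x_j ∈ g_i} w_i` with `w+_j + w−_j = 1` over the balanced
  space, averaged across imputations and banded into importance
  categories (`w+ ≥ 0.9` Highly Important, … , `< 0.4` Low).
* **Multiple imputation by bootstrap + EM** under a multivariate-normal
  working model (`m = 5` copies by default), with Rubin's-rules pooling
  `W + (1 + 1/m)B` and a stacked weighted-likelihood variant using
  `w = (1 − f)/m`, `f` being the missing-cell fraction of the n×p
  predictor grid.
* **Group-deletion influence diagnostics** — DFBETAS (cutoff `2/√n`) and
  Cook's distance (cutoff `4/n`) by full refit per deleted subject, plus
  a significance-change test for flagged subjects.
* **Forecast accuracy** — ME, MAD, RMSE, MPE (proportion), MAPE (%),
  and Nakagawa marginal/conditional R², with a sub-10% MAPE objective.
* **Synthetic cohort generator** with known ground truth (fixed effects,
  random-effect variances, MCAR/MAR missingness), emulating the study
  structure (150 subjects, visit weeks 0/13/26/52/104, age 78.9 ± 7.3,
  baseline VA 53.5 ± 24.0 left / 48.4 ± 24.3 right, treatment-drug
  missingness 35.6%, …), so every stage is testable without any data
  download.

## Worked example

```r
library(rivlmm)

cand <- c("baseline_va_le", "time_weeks", "treatment_quantity",
          "irf", "gender", "smokerpacks")
cfg <- pipeline_config(
  cohort      = cohort_config(seed = 42),   # 150-subject synthetic cohort
  candidates  = cand,
  final_model = intersect(default_final_model(), cand),
  seed        = 42)
bundle <- run_pipeline(cfg)
bundle
#> <pipeline_bundle>
#>   m = 5 imputations | 6 candidates | rule 'half'
#>   selected predictors: {baseline_va_le, time_weeks, treatment_quantity, irf}
#>   importance (averaged w+):
#>            variable   average         category
#>      baseline_va_le 1.0000000 Highly Important
#>          time_weeks 1.0000000 Highly Important
#>                 irf 0.9699734 Highly Important
#>  treatment_quantity 0.8723160        Important
#>         smokerpacks 0.3572451              Low
#>              gender 0.3567623              Low
```

The generator's truth gives baseline VA, time, treatment quantity and IRF
real effects while gender and pack-years are pure noise — and the averaged
inclusion weights recover exactly that ordering: the informative variables
have `w+` near 1, the noise variables sit in the Low band near the ~0.36
baseline that an uninformative variable earns from the balanced space.

```r
bundle$forecast$per_imputation[[1]]
#> <forecast_report> n = 750 pairs
#>   ME 0.0000 | MAD 2.6499 | RMSE 3.3639 | MPE -0.0098 | MAPE 6.30%
#>   R2 marginal 0.607 | conditional 0.920 | MAPE < 10%: yes
bundle$influence
#> <influence_report> 150 groups
#>   DFBETAS cutoff 0.1633: 37 group(s) flagged
#>   Cook's cutoff 0.0267: 7 group(s) flagged
#>   significance flips after deletion: none
```

In-sample MAPE of 6.3% meets the sub-10% objective; a mean error of ~0
says the model is unbiased; the conditional R² (0.92) far above the
marginal (0.61) quantifies how much of VA is subject-specific rather than
explained by the fixed predictors. Several subjects exceed the
rule-of-thumb influence cutoffs, but deleting any of them flips no
significance verdict — potentially influential, none overly influential.

`report_tables(bundle, "out_dir")` writes the CSV analogues of the
pipeline's tables (per-imputation w+/w− with averages, ranked importance
categories, forecast metrics, DFBETAS/Cook's values, residual and Q–Q
points) plus a JSON run manifest. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

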