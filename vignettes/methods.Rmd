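---
title: "Methods: mixed-model selection and variable importance for anti-VEGF visual-acuity response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model selection and variable importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with neovascular age-related macular degeneration receive
intravitreal anti-VEGF injections, and their visual acuity (VA, measured in
ETDRS letters) is followed over time. Clinical response is heterogeneous:
some patients maintain or gain letters, others lose vision despite
treatment. `rivlmm` implements a complete, testable pipeline for two
questions about such longitudinal cohorts:

1. **Prediction** — how well can follow-up VA be predicted from baseline
   clinical, imaging, demographic and treatment variables?
2. **Attribution** — which of those candidate predictors matter, and by
   how much, relative to one another?

The pipeline is: simulate or ingest a long-format cohort, impute missing
predictor values multiple times, exhaustively search the fixed-effect model
space of a linear mixed model on each imputed copy, combine selections
across copies, compute Akaike-weight relative importance of variables
(RIV), run group-deletion influence diagnostics on the chosen model, and
report forecast-accuracy metrics.

## The model

For subject $i$ with $n_i$ visits,

$$Y_i = X_i\beta + Z_i u_i + \varepsilon_i,$$

where $Y_i$ is the vector of follow-up VA values, $X_i$ the fixed-effect
design (an intercept plus any subset of the candidate predictors), and
$Z_i = [1, t_i]$ carries a per-subject random intercept and random slope in
time — the `(time_weeks | subject_id)` structure, with the intercept and
slope allowed to correlate. Residuals are independent Gaussian.

All fits maximise the full ML likelihood (`lme4::lmer`, `REML = FALSE`).
REML likelihoods are not comparable between models with different fixed
effects, and the entire point of the search is AIC/BIC comparison across
fixed-effect subsets, so ML is the only defensible choice; the package
never fits REML.

The parameter count used in the information criteria is
$K = p_{\text{fixed}} + 3 + 1$: the fixed coefficients (categorical
predictors contribute one coefficient per non-reference level), the three
random-effect (co)variance parameters, and the residual variance. For BIC,
$n$ is ambiguous in clustered data; the package defaults to the number of
subjects (the independent sampling units), and `information_criteria()`
takes `n_for_bic` so either convention can be requested explicitly.

### Model search and Akaike-weight importance

`enumerate_model_space()` builds all $2^k$ predictor subsets (bitmasks
internally, so the full 19-candidate space of 524,288 models enumerates
immediately), ordered by size then lexicographically. Every candidate
appears in exactly half the models — the balance that makes inclusion
weights a fair contest between variables.

For each fitted model, $\Delta_i = \mathrm{AIC}_i - \mathrm{AIC}_{\min}$
and $w_i = e^{-\Delta_i/2}/\sum_r e^{-\Delta_r/2}$, computed with the
log-sum-exp shift so that large $\Delta$ cannot underflow the
normalisation. A variable's importance is
$w_{+j} = \sum_{i:\,x_j \in g_i} w_i$, with $w_{-j} = 1 - w_{+j}$; weights
are computed per imputed dataset and then averaged across the $m$ copies
(the per-copy spread is retained so single-copy anomalies stay visible).
Averaged $w_+$ is banded into importance categories on left-closed
intervals: $\ge 0.9$ Highly Important, $[0.7, 0.9)$ Important,
$[0.5, 0.7)$ Moderate, $[0.4, 0.5)$ Low to Moderate, $< 0.4$ Low.

Non-converged fits are retained in the search record with infinite
AIC, which gives them Akaike weight zero; if more than 1% of a space
fails, the search warns, because failures unbalance the inclusion/exclusion
contest. Ties in the ranking are broken by smaller $K$, then by
enumeration order.

`model_averaged_effects()` reports conditional model-averaged
coefficients: the $w_i$-weighted mean over the models containing a
variable, renormalised by $w_{+j}$.

## Missing data

### Mechanism emulated

The generator masks predictors missing-completely-at-random by default, at
per-variable rates profiled on the study cohort (nothing missing in age,
gender, hypertension, pack-years, baseline VA or the treated eye; a few
percent in demographics and treatment counts; 18–36% in the OCT-derived
gradings and the treatment drug). An optional missing-at-random hook makes
the masking probability depend on a covariate (subjects above its median
are masked at twice the rate) while preserving the marginal rate, which is
what multiple-imputation validity arguments actually require.

### EMB imputation

`impute_emb()` follows the bootstrap-plus-EM recipe: for each of $m$
copies, resample subjects with replacement, estimate the mean and
covariance of the predictor grid under a multivariate-normal working model
by EM (`em_fit()`), and draw each subject's missing cells once from the
conditional normal given that subject's observed cells under the bootstrap
parameters. Observed cells are never altered. The default is $m = 5$.

The working model needs a numeric encoding: binary variables as
$\{0,1\}$, nominal variables as a dummy block with the reference level
dropped, ordinal-ish categories likewise. Imputed dummy blocks are decoded
to the nearest level vertex, binaries thresholded at $1/2$, bounded
continuous variables clipped (VA to $[0,100]$ letters, pack-years at 0).
Only predictors are imputed by default — rows with a missing response are
dropped at fit time, which the mixed model tolerates — but
`include_response = TRUE` adds the per-visit response columns to the EM
grid for cohorts where imputing the outcome is wanted. `time_weeks` is the
visit schedule, not a measured covariate, so a masked week is restored
deterministically from the subject's position in the schedule rather than
drawn from the normal model.

Numerical choices: EM stops when the relative change in observed-data
log-likelihood falls below $10^{-6}$ (cap 500 iterations); a
non-positive-definite covariance is repaired by an escalating diagonal
ridge starting at $10^{-8}$, and near-singular observed blocks are solved
with the same escalating-ridge guard. Degenerate bootstrap samples (a
constant column) are redrawn with a shifted seed, up to five retries.
Per-copy seeds derive from the master seed by fixed offsets, so every
stage is reproducible.

### Pooling and stacking

`rubin_pool()` combines per-copy estimates: pooled mean, between-copy
variance $B$, total variance $W + (1 + 1/m)B$. The stacked variant
concatenates the $m$ copies and fits a single model whose log-likelihood
is scaled by $w = (1-f)/m$, with $f$ the fraction of missing cells over
the $n \times p$ predictor grid (a predictor's subject-cell counts as
missing when any of its per-row cells is). Because a single scalar weight
multiplies every observation's log-likelihood contribution, the ML point
estimates equal the unweighted ones and the fixed-effect covariance is
inflated by $1/w$; the package implements the weight exactly that way
(`loglik <- w * loglik`, `vcov <- vcov / w`) rather than through `lmer`'s
precision weights, which have different semantics.

One design point deserves emphasis: the stacked table describes
$m \times n$ individuals. Each copy's subjects become distinct grouping
units in the random-effects structure. If the same subject id were reused
across copies, the random intercept would absorb the between-copy
variation of imputed subject-level covariates and shrink their fixed
effects toward zero — an artifact we observed and removed by suffixing the
subject ids per copy (the original id is kept in `source_subject`).

## Influence diagnostics

Influence is assessed at the subject level by full deletion refits — no
one-step or hat-matrix approximations; one round of refits is shared by
all three diagnostics:

* **DFBETAS**: $(\hat\gamma_i - \hat\gamma_{i(-j)})/\mathrm{se}(\hat\gamma_{i(-j)})$
  per parameter $i$ and deleted subject $j$; cutoff $2/\sqrt{n}$.
* **Cook's distance**:
  $C_j = (\hat\gamma - \hat\gamma_{(-j)})^\top \hat\Sigma^{-1} (\hat\gamma - \hat\gamma_{(-j)}) / (r{+}1)$
  with $\hat\Sigma$ the fixed-effect covariance of the full fit and
  $r{+}1$ the number of fixed-effect parameters; cutoff $4/n$.
* **Significance change**: for each flagged subject, the Wald verdict
  $|\hat\beta/\mathrm{se}| \ge 1.96$ per parameter, with and without the
  subject; only a flipped verdict marks a subject as overly influential.

In both cutoffs $n$ is the number of subjects actually in the fit, and the
report always states the $n$ used. The DFBETAS cutoff follows the
standard Belsley $2/\sqrt{n}$ rule. The 1.96 critical value is the normal
approximation; it is a configurable argument.

## Forecast evaluation

With $e_t = Y_t - \hat Y_t$: $\mathrm{ME} = \bar e$ (bias; negative under
over-forecasting), $\mathrm{MAD} = \overline{|e|}$,
$\mathrm{RMSE} = \sqrt{\overline{e^2}}$, $\mathrm{MPE} = \overline{e/Y}$
reported as a proportion, and $\mathrm{MAPE} = \overline{|e|/Y} \times 100$
as a percentage — the two percentage metrics deliberately sit on different
scales because that is how they are conventionally printed. Observations
equal to zero are excluded from the percentage metrics and counted (VA can
legitimately be 0 letters). Evaluation is in-sample against subject-level
fitted values (fixed effects plus predicted random effects) by default,
matching the definition of $\hat Y_t$ as the fitted value; the working
target is MAPE below 10%.

## The synthetic cohort generator

The generator is a first-class module, not a test fixture: it produces
cohorts with known ground truth so every downstream stage can be verified
by parameter recovery.

Defaults describe the emulated study: 150 subjects (one treated eye each)
at baseline and 3, 6, 12 and 24 months — weeks 0, 13, 26, 52, 104 at
~4.33 weeks/month. Baseline predictors are drawn from the reported
marginals (age $78.9 \pm 7.3$ years; baseline VA $53.5 \pm 24.0$ letters
left, $48.4 \pm 24.3$ right; 56.7% female; 68% hypertensive; 81.3%
ranibizumab; four-level smoking status; three-level parental ethnicities).
Summary statistics for central macular thickness, PED prevalence and
injection counts are not available from the study tables, so realistic
values were fixed once: CMT $300 \pm 60\,\mu m$, PED present 55%,
$8 \pm 3$ injections over two years.

VA is generated from the mixed model itself: random intercept SD 8
letters, random slope SD 0.05 letters/week (correlation $-0.25$), residual
SD 4 letters, and a truth vector in which the ten predictors of the
default prediction model (both baseline acuities, IRF, CMT, time,
treatment quantity and drug, treated eye, haemorrhage, PED) carry non-zero
coefficients and the remaining nine candidates are pure noise. Responses
are clipped to $[0, 100]$ letters; under the defaults clipping touches
well under 1% of rows, so tests are not distorted by truncation.

What the generator does **not** emulate: OCT images (IRF/PED/SRF are
generated directly as labels), informative dropout, visit-window jitter,
measurement error correlated with disease severity, and bilateral
treatment (eyes within a subject would share the subject's random
effects; the default gives each subject one treated-eye series, and
per-eye reporting splits subjects by treated eye). Passing tests therefore
demonstrate correctness of the machinery under the stated generating
model, not robustness to every feature of real clinic data.

## Simulation sizes used by the test suite

The property checks run at sizes chosen for a desk-scale suite, stated
here as the package's own choices: weight normalisation on a fully
enumerated 4-candidate space (16 fits); MAPE objective over 20 seeds at
the full 150-subject default; brute-force influence equivalence at 30
subjects; Rubin-pooling recovery over 100 replicates at 60 subjects with a
six-variable predictor panel masked to a missing-cell fraction near 0.1;
importance discrimination (a 0.8-standardised-SD effect versus pure noise,
$k = 6$, $m = 5$, 150 subjects) over 20 replicates with a 95% win
threshold. The exhaustive 19-candidate enumeration is exercised as an
enumeration (no fits); searching all 524,288 models per imputed copy is
supported but guarded behind `allow_large`, with a default cap of
$2^{12}$ models per search.

## Known limitations

* The multivariate-normal working model imputes dummy-coded categoricals
  by nearest-vertex rounding; with very rare levels and small cohorts the
  bootstrap can miss a level entirely (the retry guard then re-draws).
* Exhaustive search cost grows as $2^k$ fits per imputed copy; there are
  deliberately no stepwise or branch-and-bound shortcuts.
* Forecast metrics are in-sample by default; a held-out evaluation exists
  (`evaluate_fit(fit, table)`) but is not the reported default.
* No generalized (non-Gaussian) responses, crossed random effects, or
  autoregressive residuals; no MNAR sensitivity analysis and no
  chained-equations imputation engine.
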