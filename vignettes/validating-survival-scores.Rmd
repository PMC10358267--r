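---
title: "Validating preoperative survival scores at fixed horizons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating preoperative survival scores at fixed horizons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients undergoing surgery for extremity bone metastasis have limited and
highly variable life expectancy, and the choice between palliative fixation
and extensive resection/reconstruction hinges on how long the patient is
likely to live. A number of preoperative scoring systems (PSSs) map
preoperative features — demographics, tumor burden, performance status,
laboratory values — to a survival prediction at fixed post-operative
horizons (1, 3, 6, 12, 18, 24 months). Some emit a survival probability;
others only an integer score.

`pssval` implements the machinery to *externally validate* such systems on
a cohort: horizon-status ascertainment, discrimination, Brier score against
the prevalence (null) model, logistic-recalibration calibration, the
observed:expected survivor ratio, decision curves, and a model-consistency
statistic. Because real cohorts of this kind are rarely shareable, the
package also ships a synthetic-cohort generator calibrated to the marginal
structure of a 356-patient surgical cohort, so every stage of the pipeline
can be exercised and tested end to end without patient data.

```{r, eval = FALSE}
library(pssval)
cfg <- sim_config(frailty_sd = 1.5)
sim <- generate_cohort(cfg, list(
  pred_sim_spec("well_calibrated", noise_sd = 0.8),
  pred_sim_spec("underestimates", shift = 0.8, noise_sd = 0.8)), seed = 7)
report <- run_validation(sim$cohort, sim$predictions,
                         run_config(n_boot = 500, seed = 7))
format_report(report, "table2")
```

## Horizon status and ascertainment

All metrics are computed at fixed horizons. A patient is `DEAD` at horizon
$t$ if death was observed at or before $t$, `ALIVE` if follow-up reached
$t$, and `UNKNOWN` if censored alive before $t$. Two boundary rules are
fixed once and used everywhere, including the simulator's calibration: a
death recorded exactly at the horizon counts as `DEAD`, censoring exactly
at the horizon as `ALIVE`. Every metric is complete-case per horizon:
`UNKNOWN` patients are dropped, so denominators are the per-horizon
ascertained counts. Inverse-probability-of-censoring weighting would be
the natural extension but is deliberately out of scope; with only
5–15% of statuses unascertainable at the study conditions, the
complete-case estimates are what the validation literature typically
reports.

One consequence worth knowing: dropping `UNKNOWN` patients selects against
survivors (only patients alive can be lost to follow-up), which biases the
calibration-in-the-large intercept slightly negative — about $-0.09$ at
the default dropout rates. This is a property of per-horizon complete-case
analysis itself, not of the implementation; the parameter-recovery tests
therefore run under full ascertainment.

## The metrics

**Discrimination.** The horizon c-index is the probability that a random
survivor received a higher predicted survival value than a random
non-survivor, ties counting one half. It is computed from ranks in
$O(n\log n)$ and the test suite checks it exactly against a brute-force
$O(n^2)$ pairwise count. Because it is rank-based it applies unchanged to
integer-score models. CIs are a stratified bootstrap (2000 resamples by
default), resampling survivors and non-survivors separately.

**Brier score.** $\frac1n\sum_i(\hat p_i - y_i)^2$ with $y_i$ the alive
indicator. The benchmark is the null model that predicts the prevalence
$\bar p$ for everyone, whose Brier score is $\bar p(1-\bar p)$; a useful
model sits below it, and the size of the reduction is comparable across
models on the same cohort.

**Calibration.** Predictions are clamped to $[\varepsilon, 1-\varepsilon]$
($\varepsilon = 10^{-6}$) before logits. The slope is the coefficient of
$\operatorname{logit}\hat p$ in a logistic recalibration of the alive
indicator (1 is ideal, $<1$ means over-extreme predictions); the headline
intercept is calibration-in-the-large, fitted with
$\operatorname{logit}\hat p$ as an offset, so a positive value means the
model underestimates survival. `calibration_fit()` additionally returns
the intercept of the *joint* recalibration fit: when the slope differs
from 1 the offset-model intercept is not the generating shift (a shift of
$-1$ at slope $0.5$ yields a calibration-in-the-large value near $-2.4$),
while the joint intercept recovers it, so parameter-recovery checks target
the joint fit. `log(O{:}E)` uses observed survivors $O$ and expected
$E=\sum_i \hat p_i$, with the delta-method CI
$\pm 1.96\sqrt{(1-\bar p)/O}$.

**Decision curves.** Computed on the death event: predicted risk is
$1-\hat p$, a patient is classified positive when risk $\ge p_t$, and net
benefit is $TP/n - FP/n \cdot p_t/(1-p_t)$, compared against treating all
(net benefit $\to$ prevalence as $p_t \to 0$) and treating none (0). The
survival-framed curve is the mirror image and derivable from the same
output; the orientation is a recorded choice, since "risk of surgery"
axes in the clinical literature are not always explicit.

**Model consistency.** Survival probability cannot rise with the horizon
("law of attrition by time"), yet multi-horizon models can emit, say, 34%
at 6 months and 37% at 12 months. MC is the fraction of within-patient
horizon pairs with $\hat p(t_1) \ge \hat p(t_2)$ for $t_1 < t_2$; ties
count as reasonable, pairs with a missing cell are skipped, and the
violating records are returned for inspection. Score-only models without
a score map are excluded from MC, calibration, Brier and decision curves
— exactly the exclusion applied to integer-score systems in validation
practice — but keep their rank-based c-index.

## The synthetic cohort

The generator's defaults are the study conditions it emulates: 356
patients; horizon mortality 5/18/32/51/61/68% at 1/3/6/12/18/24 months
*among ascertained patients*; ascertainment 356/350/342/326/314/302;
administrative censoring at 24 months; median age 61 (range 25–95), 52%
female, median BMI 23, 60% with an extra Charlson comorbidity, ECOG 0–2
in 79%, tumor mix lung 33% / breast 16% / hepatocellular 10% / other 41%;
lab missingness rates of 0.3% (sodium) to 25% (blood urea nitrogen). Lab
marginals and the remaining covariate frequencies are physiologic
placeholders (the source summaries are not available in full) and fully
configurable; their realism is immaterial to metric correctness.

**Survival model.** Piecewise-exponential with knots at the six horizons —
the simplest family that can match all printed targets exactly. Because
the printed mortality fractions are deaths over *ascertained* patients,
the death and dropout hazards of each inter-horizon interval are solved
jointly: with $D(t)$ the expected observed-death fraction and $SG(t)$ the
expected at-risk fraction, the interval's total attrition rate is
$\theta = -\Delta\log SG/\Delta t$ and the death share follows in closed
form from $\Delta D$. With full ascertainment this reduces to
$\lambda_k = -\Delta \log S(t_k)/\Delta t_k$ on the cumulative survival
targets. In covariate-linked mode (or with a frailty) the same two
constraints are solved per interval by nested one-dimensional
root-finding over the sampled linear predictors. Acceptance checks verify
that 200 replicate cohorts reproduce the six mortality targets within
±0.01.

**Heterogeneity.** A marginal cohort gives every patient the same true
survival curve, so no prediction model can discriminate on it. The config
therefore has an optional log-normal frailty (`frailty_sd`, default 0 to
keep the plain marginal model) and/or user-supplied proportional-hazards
coefficients. `frailty_sd = 1.5` yields a truth whose 12-month
discrimination is about 0.88, leaving headroom for prediction models
targeting AUCs in the published 0.6–0.85 range.

**Synthetic prediction models.** Predictions distort the latent truth as
$\hat p_i(t) = \operatorname{expit}\!\big(
(\operatorname{logit} p_i(t) - a - e_i)/b \big)$ with a single
patient-level noise term $e_i \sim N(0, \sigma^2)$ shared across horizons.
$(a, b)$ are parameterized on the *recalibration scale*: fitting
calibration against outcomes drawn from the truth recovers intercept $a$
and slope $b$, and a positive $a$ produces underestimation, matching the
reporting convention. (The alternative "direct" parameterization
$\hat p = \operatorname{expit}(a + b\operatorname{logit} p + e)$ would
recover $-a/b$ and $1/b$ instead, which makes recovery tests incoherent;
this was a deliberate design choice.) Patient-level — rather than
per-cell — noise keeps synthetic models internally consistent, so MC is
exactly 1 whenever $b > 0$; deliberate MC violations are injected with
`horizon_noise_sd`. When a target AUC is requested, $\sigma$ is solved by
bisection on a fixed noise draw against 50,000 patients resampled from
the truth's empirical distribution, to within 0.005. Score-mode models
quantile-bin the latent predictor into integer levels.

**Missingness.** MCAR per lab by default; `mar_ecog = TRUE` scales each
patient's missingness probability with $1 + \text{ECOG}/2$, renormalized
to preserve the marginal rate, because iterative imputation behaves
differently under MAR.

## Imputation

`impute_missforest()` implements the iterative random-forest imputation
loop: mean-fill initialization, variables visited in ascending order of
missingness (ties by column position), a 100-tree regression forest per
lab fitted on rows where it was observed, and the canonical stopping rule
— quit when the normalized squared difference between successive
imputations first increases, returning the previous iteration. Only the
ten labs are imputation targets; all other covariates serve as
predictors. Forests run single-threaded with derived seeds, so runs are
bit-reproducible. The published analysis names the algorithm but not its
hyperparameters; ensemble size 100 and default tree parameters are
declared choices, recorded in the function signature. On synthetic labs
with a built-in 0.8 correlation and 25% MCAR missingness, the forest
imputation beats mean fill (RMSE against the withheld truth) in
essentially every seed; the complete-case subset
(`complete_case_subset()`) supports the sensitivity re-analysis.

## Numerical choices and degenerate inputs

- Probability clamp $\varepsilon = 10^{-6}$ before any logit; AUC ties
  count one half; report tables round to 2 decimals.
- Constant predictions: the calibration slope is undefined (`NA`,
  flagged) while intercept and log(O:E) are still returned; the
  calibration curve collapses to one bin.
- Single-class horizons (no deaths, or no survivors) raise an error
  rather than returning a vacuous AUC.
- Hazard calibration rejects infeasible targets (at-risk fraction rising,
  deaths without attrition) naming the offending interval; zero-mortality
  targets yield exactly zero death hazards.
- Root-finding tolerances are $10^{-12}$ on interval probabilities;
  bootstrap and simulation results are bit-reproducible given seeds.

## Problem sizes

The shipped tests and the acceptance script use cohorts of 120–356 for
pipeline behavior, 20,000 for calibration parameter recovery (recovered
intercept/slope within ±0.1 over shifts $\{-1,0,1\}$ × slopes
$\{0.5,1,1.5\}$), 50,000 for AUC-target construction, 200 replicate
cohorts for simulator calibration, and 20 seeds for the imputation
benchmark — sizes at which Monte Carlo error is comfortably below the
asserted tolerances.

## Limitations

- The generator matches marginal structure (mortality, ascertainment,
  covariate frequencies, missingness rates) but not the joint
  covariate–survival dependence of any real cohort; passing tests
  demonstrate correctness of the metric machinery, not clinical realism.
- By default labs are independent (identity copula) and survival does not
  depend on tumor type; both can be switched on via the config but no
  attempt is made to make them realistic.
- No time-to-event concordance over the full follow-up (Harrell's C),
  no net-benefit confidence bands, and no IPCW handling of censoring —
  fixed-horizon complete-case analysis only.
- The score→probability map for integer-score systems must be supplied by
  the user; published score systems rarely document one, and none is
  invented here.
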