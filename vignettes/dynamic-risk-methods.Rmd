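---
title: "Methods: two-stage dynamic prediction of lifetime AD risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage dynamic prediction of lifetime AD risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogdynrisk)
```

## The problem

In ageing cohorts with annual neuropsychological assessment, each subject
accumulates a growing history of cognitive-domain composite scores. The
question this package addresses is *dynamic* lifetime risk prediction: at
every landmark year $t$ after enrolment, estimate each subject's
probability of developing Alzheimer's disease (AD) before death using only
the measurements observed by year $t$, and quantify how discrimination
improves as the history lengthens.

The binary outcome (incident AD before death versus remaining cognitively
intact) is fixed per subject; the landmark trims the *predictor* history,
never the outcome. Competing risk of death is deliberately not modelled:
death without AD simply contributes an outcome of zero, and the age-bounded
variants (risk of onset before 85 or 90) restrict the cohort so that the
outcome is resolved by the cut age.

## The two-stage estimator

**Stage 1 — trajectory summaries.** For each cognitive domain $d$, a linear
mixed model with random intercept and slope is fitted by restricted maximum
likelihood (REML) to all visits in the landmark window:

$$y_{ij} = x_{ij}'\beta + b_{0i} + b_{1i}\,t_{ij} + e_{ij},
\qquad (b_{0i}, b_{1i}) \sim N(0, G),\quad e_{ij} \sim N(0, \sigma^2),$$

where $t_{ij}$ is years since baseline and the fixed covariates are an
intercept, time, baseline age, sex (female = 1) and ordinal education
(0–3). Each subject's random effects are then predicted by the empirical
best linear unbiased predictor (EBLUP)

$$\hat b_i = G Z_i' V_i^{-1} (y_i - X_i\hat\beta), \qquad
V_i = Z_i G Z_i' + \sigma^2 I,$$

which shrinks noisy or short histories toward the population mean. Missing
visits and missing domain scores are handled by simply omitting those rows;
no imputation is performed.

**Stage 2 — risk model.** The per-domain intercept and slope summaries,
together with baseline age, sex and education, enter a logistic regression
for the binary outcome, fitted by maximum likelihood. Plug-in of stage-1
point estimates is deliberate: stage-1 uncertainty is not propagated, which
matches the two-stage estimator this package implements and keeps the risk
model an ordinary logistic regression. Both stages are refitted from
scratch at every landmark year, so "updating the prediction" is realised as
annual refits.

The slope variable is years since baseline rather than age; baseline age is
a fixed covariate. This keeps random slopes comparable across subjects who
enrol at different ages. Fixed effects are main effects only.

## Estimation details and numerical choices

* $G$ is parameterised relative to $\sigma^2$ through its Cholesky factor
  $L$ ($G = \sigma^2 L L'$) with the diagonal of $L$ bounded below at zero,
  so the $G = 0$ boundary is attainable — a log-parameterisation cannot
  represent a zero variance, and degenerate fits (noise-free data, pinned
  slope variance) are part of the contract. $\beta$ and $\sigma^2$ are
  profiled out in closed form; the optimizer (`nlminb`) works on the three
  free Cholesky parameters with convergence tolerances of $10^{-12}$
  relative change. A solution reported by the optimizer with a spurious
  "false convergence" code is accepted only if no coordinate probe of size
  $10^{-3}$ improves the profiled objective.
* Each REML evaluation uses the Woodbury identity on the 2-dimensional
  random-effect space, reducing all linear algebra to closed-form
  $2 \times 2$ operations on per-subject cross-products. Subjects sharing a
  visit-time pattern share their whitening matrix, so the objective is
  evaluated from visit-pattern *group* aggregates. Under subject-level
  bootstrap resampling the aggregates change only through multiplicity
  weights, making a full pipeline refit per resample cheap; the weighted
  fit is algebraically identical to refitting on the stacked resampled
  rows, and the test suite verifies this equality against the row-level
  implementation.
* At landmark 0 every subject has a single visit: the random-slope variance
  is unidentified and pinned at zero (flagged), the constant time column is
  dropped from the fixed effects, and the all-zero slope summaries are
  excluded from stage 2 with coefficients fixed at zero.
* Stage 2 uses iteratively reweighted least squares with a weighted QR
  inner solve, step-halving, and convergence declared when the score
  satisfies $\max_j |X'(y-\mu)|_j < 10^{-8}$ in the column-scaled basis.
  At early landmarks the intercept and slope summaries of a domain are
  nearly (or, when the slope variance collapses to a rank-one $G$, exactly)
  collinear; aliased columns are detected by pivoted QR and fixed at zero,
  exactly as `lm()` handles aliased terms. Quasi-separation is flagged when
  a fitted log-odds passes 30 in absolute value — a coefficient-magnitude
  rule would misfire on the tiny-scale slope summaries.
* Subjects missing an entire domain under a multi-domain model are dropped
  from stage 2 (tallied); `impute_missing_zero = TRUE` instead shrinks their
  missing summaries fully to the population mean of zero.

## Evaluation machinery

* **AUC(t)** is the Mann–Whitney rank estimator (ties count one half),
  exact against pair enumeration.
* **Bootstrap validation** resamples subjects with replacement (whole visit
  histories travel with the subject; duplicates are distinct), refits the
  *entire* two-stage pipeline per resample, and records the refit model's
  AUC on its resample. The interval is the *reflected* (basic) bootstrap:
  the 2.5/97.5 quantiles of the replicate distribution mirrored around the
  original-sample AUC. The reflection matters: each replicate scores a
  model on the very resample it was fitted to, so the replicate
  distribution is shifted upward by roughly one optimism unit relative to
  the point estimate, and raw percentile endpoints inherit that shift.
  In a coverage experiment under the generator (intervals at n = 400,
  B = 200, against the same pipeline's AUC at n = 20000), raw percentile
  intervals covered in 84% of replications and reflected intervals in
  93% — the reflection restores near-nominal coverage, which is why it is
  the package default. Resamples with a single outcome class or a
  failed/flagged fit are redrawn, capped at 20% of the replicate count.
  The default is 1000 replicates; a fast re-scoring mode
  (`refit = FALSE`) resamples the original fit's risk scores without
  refitting. Refitting per resample is the conservative reading of
  internal validation.
* **DeLong's test** for two correlated AUCs uses midrank placement values;
  its variance is verified against direct placement enumeration and an
  independent implementation.
* **Calibration** is assessed by the Brier score and a decile calibration
  table (quantile bins, ties to the lower bin); the Brier score is reported
  per landmark rather than privileging a single year.
* **Stepwise domain selection** is greedy forward selection on the
  landmark-10 AUC with a minimum-improvement threshold of 0.001
  (configurable). Selection compares original-sample AUCs of refitted
  pipelines; bootstrap intervals can be attached to the selected path.

## The synthetic cohort generator

Restricted-access cohort data cannot ship with the package, so every
analysis is driven by a simulator whose ground truth is known. The
generator emulates the *structure* of a large US ageing cohort: baseline
age $\sim N(77.5, 7.5^2)$ years, 75.5% women, four education levels with
probabilities (0.047, 0.131, 0.178, 0.644), five z-scored domain composites
with per-domain random intercept/slope covariance
$\begin{pmatrix}0.30 & -0.008\\ -0.008 & 0.004\end{pmatrix}$ (z², z²/yr²),
residual SD 0.35 z, equicorrelation 0.5 of random effects across domains,
annual visits capped at 11, per-year dropout hazard 0.012, and a Gompertz
death hazard ($0.028\,e^{0.09(a-77.5)}$ per year). The lifetime AD
indicator is drawn from a logistic model *of the same functional form as
the analysis model* — true random effects plus demographics — so parameter
recovery is well-posed; defaults put most signal on the slopes
($\gamma_{b1} = -5.5$ per domain, $\gamma_{b0} = -0.25$, age $+0.04$/yr,
education $-0.05$).

Onset for cases is placed at a Beta-distributed fraction of the survival
time, $\mathrm{Beta}(4.5\,e^{-0.5\,\mathrm{decline}},\ 1.5)$ of the time to
death, so onset falls late in life, always strictly between baseline and
death, and faster decliners convert earlier. This placement is a generator
convention — the outcome definition constrains only that onset precede
death. Visits stop strictly before onset for cases, matching the analysis
rule that only pre-onset assessments are used.

These defaults were fixed once, by simulation, to reproduce the qualitative
behaviour the analysis is designed to exhibit: roughly a quarter of
subjects developing AD, a mean of 7–8 visits per subject, and a landmark
AUC that rises steadily from about 0.59 at baseline to about 0.73 at year
10 as slope information accrues. They are conditions for property-based
testing, not estimates of any real cohort's parameters. What the generator
does *not* emulate: item-level psychometrics (raw tests are affine images
of the composites plus noise), practice effects, informative dropout
(dropout is independent of cognition), death–cognition dependence, and MCI
as an explicit state (only the flags the eligibility filters consume are
emitted). Passing tests therefore demonstrate correctness of the machinery
and recovery under the stated generative model, not clinical performance on
real data.

## Eligibility and dataset construction conventions

* Lifetime filters run in a fixed order — baseline impairment, non-AD
  dementia, MCI more than 10 years after baseline in non-progressors, no
  clinical evaluation, missing covariates — and each subject is tallied at
  the first rule that removes it. Non-progressors with MCI *within* 10
  years are retained, the literal reading of the rule; the log/tally makes
  the count visible.
* "Prior to onset" is a strict inequality on age at visit versus onset age;
  an assessment in the onset year itself is excluded.
* The 11-visit cap keeps the earliest qualifying visits.
* Composite standardization is anchored to the baseline-visit mean/SD of
  the analysis cohort and reused at later visits, keeping later scores on
  the baseline scale; the constants are returned for reuse.
* Education enters as a single ordinal covariate (0–3) rather than dummy
  indicators, matching a single reported education effect; the encoding is
  documented in the generator/config schema.
* In the age-bounded variants, intact subjects with no recorded death are
  retained only if last contact is past the cut age; otherwise their
  outcome before the cut is unresolved and they are removed with their own
  tally (`unresolved_before_cut`). The generator records full lifetimes, so
  this path matters only for external data.

## Problem sizes used by the test and acceptance suites

The property-based checks run at sizes chosen to give stable Monte-Carlo
margins: REML recovery at 1000 subjects × 8 visits over 10 seeds (with
time-varying, well-spread covariates in the recovery design — a coefficient
of 0.01 on a subject-constant covariate is not identifiable to 10% under an
intercept SD of 0.5 at that n, so identification scale is part of the
design); stage-2 recovery at n = 5000 against the generator's true random
effects; the qualitative AUC(t) trend on five cohorts of n = 2000 with 100
bootstrap replicates per year; DeLong type-I error from 1000 null
simulations at n = 200; decile self-calibration of the true generating
probabilities at n = 5000; and bootstrap coverage from 100 replications at
n = 400 with B = 200 against a single-domain reference pipeline fitted at
n = 20000. The zero-signal null control is evaluated *out of sample* (a
pipeline fitted on one null cohort of n = 1000 scores an independent one):
the resubstitution AUC of a 14-parameter model sits several bootstrap SDs
above 0.5 under the null at any n — overfitting, not discrimination — so
only held-out scores test the null property. The acceptance script reports
the full annual AUC table at n = 2000 with B = 200.

## Known limitations

* Stage-1 uncertainty is not propagated into stage 2; standard errors of
  stage-2 coefficients are conditional on the trajectory summaries.
* No optimism correction is applied inside the bootstrap: the reported AUC
  is the original-sample (apparent) AUC with a resampling interval, so at
  small n it inherits the optimism of resubstitution.
* Lifetime risk ignores the competing risk of death by design; the
  age-bounded variants are the supported mitigation.
* The horizon designs (onset 5/10 years after the last included visit) drop
  subjects without qualifying visits, which conditions the cohort on
  surviving long enough — a selection effect inherent to that design.
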