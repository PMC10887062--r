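---
title: "Individual survival distributions with MTLR: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual survival distributions with MTLR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isdkit)
```

## The problem

Population survival analysis summarises a cohort: a Cox model returns one
hazard ratio per covariate, and a Kaplan–Meier curve describes the group
average. An *individual survival distribution* (ISD) instead assigns every
patient a full curve $S(t \mid x)$, queryable at any future time, from which
individual medians, time-point probabilities and treatment contrasts follow
directly. `isdkit` implements an ISD workflow for clinical covariate tables
— built around gastric adenocarcinoma cohorts annotated with molecular
subtype scores, but applicable to any right-censored table — with multi-task
logistic regression (MTLR) as the central model and three classical ISD
baselines for comparison.

## The MTLR model

Time is discretised at points $\tau_1 < \dots < \tau_m$ derived from the
training data: $m = \lceil \sqrt{n_{\text{uncensored}}} \rceil$, with
$\tau_j$ at the $j/(m+1)$ empirical quantiles (type 7) of the uncensored
event times, de-duplicated. The square-root rule keeps roughly
$\sqrt{n}$ events per interval as cohorts grow; quantile placement gives
each interval comparable information.

Each time point carries a logistic predictor
$\theta_j(x) = w_j \cdot x + b_j$. The probability that a patient dies in
interval $k \in \{1, \dots, m+1\}$ (intervals $(\tau_{k-1}, \tau_k]$ with
$\tau_0 = 0$, $\tau_{m+1} = \infty$) is

$$P(k \mid x) = \frac{\exp\!\big(\sum_{j \ge k} \theta_j(x)\big)}{Z(x)},
\qquad
S(\tau_j \mid x) = \sum_{k > j} P(k \mid x).$$

An uncensored patient contributes $-\log P(k(t_i) \mid x_i)$; a censored
patient contributes the log of the total mass of all intervals not
contradicted by survival to the censoring time, *including* the interval
containing it (a patient censored mid-interval may still die inside it; the
strictly-later convention is available via `censored_inclusive = FALSE`).
The negative log-likelihood is convex; we minimise it with L-BFGS from a
zero start (with a full-memory BFGS polish when the limited-memory step
stalls), so the fit is deterministic, to gradient norm
$\le 10^{-6}\max(1, |f|)$. All interval sums are computed with log-sum-exp
stabilisation.

Because the per-time weights are free, covariate effects may grow, shrink
or reverse over time, and predicted curves for two patients can cross —
the behaviour that proportional-hazards models rule out by construction.

### Regularisation

A ridge penalty $\tfrac{\lambda}{2}\lVert W\rVert_F^2$ (biases unpenalised)
is the default, with $\lambda$ chosen by inner 5-fold cross-validation of
the out-of-fold log-likelihood over $\{2^{-6}, 2^{-4}, \dots, 2^{6}\}$,
ties resolved toward the stronger penalty. Inner-CV candidate fits use a
relaxed gradient tolerance ($10^{-3}$) — penalty selection compares
out-of-fold likelihoods, which are insensitive to the final optimisation
digits — while the returned fit is always solved to the strict tolerance.

A temporal-smoothness penalty
$\tfrac{\mu}{2}\sum_j \lVert w_{j+1} - w_j \rVert^2$ is exposed
(`smooth_lambda`, default 0). It matters for one specific purpose: the raw
per-time weights of a ridge-only fit oscillate bin to bin, because the
likelihood constrains mainly their cumulative sums — adjacent weights can
trade off almost freely. Predictions, mean weights and fold-averaged
profiles are unaffected, but if the *per-bin sign* of a weight trajectory
is of interest (e.g. checking that a harmful covariate is harmful at every
time), a smoothed fit with $\mu \approx 2n$ recovers coherent
trajectories. We use that setting for sign-level diagnostics and leave it
off everywhere else, which also mirrors the common practice of smoothing
weight profiles for display.

## Baseline ISD models

* **Cox-KP** — Cox partial likelihood (Breslow ties, via
  `survival::coxph`) plus the Kalbfleisch–Prentice baseline: at each
  distinct event time the survival factor $\alpha_i$ solves
  $\sum_{i \in D} e^{\eta_i} / (1 - \alpha^{e^{\eta_i}}) =
  \sum_{l \in R} e^{\eta_l}$ (closed form for untied events, bisection via
  `uniroot` for ties). At $\beta = 0$ this is exactly Kaplan–Meier, which
  the tests assert step for step. ISD: $S(t \mid x) = S_0(t)^{\exp(\beta x)}$.
* **CoxEN-KP** — the same with elastic-net regularisation of the partial
  likelihood (via `glmnet`, penalty on glmnet's per-observation scale;
  mixing 0.5 by default, strength by inner CV), then the KP baseline at
  the penalised coefficients.
* **Weibull AFT** — $\log T = \mu + \gamma x + \sigma W$ with $W$ standard
  minimum extreme value (via `survival::survreg`);
  $S(t \mid x) = \exp(-(t/e^{\mu + \gamma x})^{1/\sigma})$.

A random-survival-forest column can be attached through `isd_adapter()`
without the package implementing the ensemble itself.

## Curves, medians and extrapolation

Curves are knot sets $(\tau_j, S_j)$ starting at $(0, 1)$, monotone
non-increasing. Queries use a Hyman-filtered monotone cubic Hermite spline
(`stats::splinefun(method = "hyman")`): knots are interpolated exactly,
flat segments stay flat, and no overshoot occurs. Beyond the last knot the
curve continues linearly with the final knot-segment slope, floored at 0 —
MTLR curves frequently end above 0.5, and a median would otherwise be
undefined; whether the original analyses truncated or extrapolated is not
documented, so the choice is flagged and configurable in spirit (the raw
knots are always available). The reported **median survival** is the time
at which this extended interpolant crosses $S = 0.5$ (root-bracketed to
$10^{-6}$ months; `NA` when never reached). The integral summary —
restricted mean survival time — is exposed separately as
`restricted_mean_survival()`, since "the integral of the curve at 50%
survival" admits both readings.

## Evaluation metrics

* **Concordance (Harrell)** over comparable pairs ($t_i < t_j$, patient
  $i$ uncensored), ties at half credit. The ISD-native risk score is the
  *negative predicted median survival* (negative restricted mean behind a
  flag); concordance is invariant to monotone transforms of risk.
* **1-calibration** — Hosmer–Lemeshow at an anchor time: deciles of
  predicted event probability, observed decile rates estimated by
  within-decile Kaplan–Meier (censoring-adjusted),
  $\chi^2$ with $G - 2$ df. Degenerate deciles merge with a neighbour.
  Anchors are the 10/25/50/75/90th percentiles of observed uncensored
  event times (the distribution the anchors refer to is not documented in
  the convention we follow; event times are the natural choice and the
  switch is recorded here).
* **D-calibration** — if curves are correct, $S_i(t_i)$ is Uniform(0,1).
  Uncensored patients drop unit mass into the decile containing
  $S_i(t_i)$; a censored patient with $p = S_i(c_i)$ spreads mass
  $(\min(b_{hi}, p) - b_{lo})_+ / p$ over the bins below $p$
  (conditional-uniform; $p = 0$ goes wholly to the lowest bin). Pearson
  $\chi^2$ against uniform with $n_{\text{bins}} - 1$ df.
* **Integrated Brier** — IPCW-weighted squared error with the censoring
  distribution estimated by Kaplan–Meier, trapezoid-integrated over the
  pooled event-time grid and normalised by $t_{\max}$; integration
  truncates where $G$ reaches 0.

`cross_validated_evaluation()` runs stratified 5-fold CV (event-stratified
— whether the original folds were stratified is unstated; stratification
guards small cohorts against event-free folds). Concordance and IBS are
summarised mean ± sd over folds; the calibration tests are computed once
on pooled out-of-fold predictions, because a single p-value per model is
the reporting convention.

## Interpretation layer

The $k$ fold models' weight matrices are pooled as
(covariate, fold, $\tau$, weight) triples — folds with different $m$ are
pooled as pairs, never aligned by index. From the pooled values:
mean weight per covariate with a 1000-resample percentile bootstrap CI
(resampling unit: individual (fold, $\tau$) values; whole-fold resampling
behind `by_fold`), a one-sample Wilcoxon signed-rank test against zero per
covariate (a one-sample t-test behind `test = "t"`, since both appear in
the tradition this follows; Wilcoxon is the default), Benjamini–Hochberg
adjustment across covariates, and influence ranking by absolute mean
weight (alphabetical ties). Negative weights favour survival. Weights are
reported on the standardised-covariate scale, with the scaling constants
recorded in the fit, because fold-wise standardisation makes raw-scale
weights incomparable across folds.

A Cox model fitted once on the full cohort provides the familiar
population-level reference; Pearson correlation between its coefficients
and the MTLR mean weights (with scatter data exported) quantifies the
agreement. "Counterfactual" curve pairs re-predict one patient with an
input toggled; this is a model contrast under a changed input, not a
causal estimate, and is labelled as such.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a pooled gastric
adenocarcinoma cohort of 1043 patients so that every stage of the pipeline
is testable with known truth:

* covariate marginals follow the published cohort table: stage I/II/III/IV
  at 16/32/33/20%, 66% male, 71% chemotherapy-exposed, age from a
  truncated normal (location 59, scale 13.3, range 20–90 years, matching
  a median of 59 with IQR 49–67), Lauren and tumour-location frequencies
  likewise; molecular-subtype scores are Dirichlet-distributed classifier
  probabilities (one simplex per classifier, concentration 4 — moderately
  confident classifiers), and the TME-high score is Beta(1.83, 2.17)
  (mean 0.46);
* event times come from a piecewise-exponential hazard
  $h(t \mid x) = h_0(t)\exp(\sum_c \beta_c(t) x_c)$, sampled by exact
  closed-form inversion of the cumulative hazard. Default effects encode
  the qualitative time-varying pattern of interest: chemotherapy
  protective before 24 months then null, stage IV constantly harmful,
  stage III harmful only after 12 months, a TME score whose benefit is
  strongest after 60 months, EMT harmful, with small age and sex effects;
* the baseline hazard (0.018, 0.013, 0.0075, 0.0045 per month on segments
  starting at 0, 12, 36, 72) yields a median observed survival near 28
  months — a realistic advanced-gastric-cancer figure;
* censoring is administrative at 120 months plus an independent
  Uniform(0, 120) dropout time per patient, giving ≈50% censoring at the
  defaults (the source cohort's censoring fraction is unpublished; 50% is
  a deliberately demanding default and both pieces are configurable).

Covariates are drawn independently — real molecular subtypes correlate
with stage, Lauren type and each other — and the hazard is exactly
piecewise-exponential. Passing tests therefore demonstrate correctness of
the estimators and the recovery machinery under the stated model, not
robustness to misspecification or to correlated designs.

## Problem sizes used by the validation suite

Parameter-recovery checks run at $n = 5000$ (Cox and AFT coefficients to
±0.1 and ±0.05), time-varying-effect recovery at $n = 2000$ over 5 folds,
test-calibration studies at $n = 2000$ over 50 seeds, and the end-to-end
pipeline at $n = 1000$ with all four models and 1000 bootstrap resamples,
re-run twice to confirm byte-identical outputs. These sizes give
comfortable Monte-Carlo margins for the stated tolerances while keeping
the suite quick on a laptop.

## Known limitations

* No competing risks, interval censoring, time-dependent *input*
  covariates, or stratified Cox.
* The random survival forest appears only through the adapter interface.
* Bootstrap CIs treat (fold, $\tau$) weight values as exchangeable;
  weights within a fold are correlated, so the default CI is narrower
  than a fold-level resample (available via `by_fold = TRUE`).
* The 1-calibration test is mildly anti-conservative under heavy
  censoring before the anchor (the within-group KM variance exceeds the
  binomial variance assumed by the statistic); its df convention
  ($G - 2$) follows the standard formulation.

## A short worked example

```{r example, eval = FALSE}
library(isdkit)

sim <- generate_cohort(synthetic_config(n = 1000), seed = 1)
report <- cross_validated_evaluation(
  sim$cohort, models = c("mtlr", "coxkp", "coxen", "aft"),
  k = 5, seed = 2
)
glance(report)

fit <- fit_mtlr(sim$cohort, seed = 2)
patient <- sim$cohort[1, ]
curve <- predict_survival_curve(fit, patient)
median_survival_time(curve)
survival_at_time(curve, c(24, 48))
autoplot(curve)

pair <- counterfactual_curves(fit, patient, toggle = list(treatment = "Yes"))
pair$summary
```
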