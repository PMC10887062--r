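# isdkit

Individual survival distributions (ISDs) for clinical covariate tables,
centred on **multi-task logistic regression (MTLR)**.

Population survival tools answer population questions: a Cox model yields
one hazard ratio per covariate, a Kaplan–Meier curve describes a group. An
ISD model instead hands every patient a full survival curve
*S(t | x)* — queryable at any time, summarisable as an individual median,
and contrastable under a changed input ("what does this curve look like
with chemotherapy?"). `isdkit` is built for oncology cohorts — its
simulator and default schema emulate a pooled gastric adenocarcinoma
cohort with molecular-subtype scores (TCGA, ACRG, TME classifiers) — but
works with any right-censored patient table.

## What's inside

* **MTLR** — logistic predictors θ_j(x) = w_j·x + b_j at *m* time points
  (m = ⌈√#events⌉, quantile-placed); the probability of death in interval
  *k* is exp(Σ_{j≥k} θ_j(x)) / Z(x). The censored-data negative
  log-likelihood is convex and solved by quasi-Newton with exact
  gradients; ridge penalty chosen by inner 5-fold CV. Because per-time
  weights are unconstrained, effects may vary with time and patient
  curves can cross — no proportional-hazards assumption.
* **Baselines** — Cox with Kalbfleisch–Prentice self-consistent baseline
  (reduces exactly to Kaplan–Meier at β = 0), elastic-net Cox, Weibull
  accelerated failure time; an adapter slot for external models (e.g. a
  random survival forest).
* **Curve machinery** — Hyman-filtered monotone cubic splines for
  survival queries, median survival by root bracketing, restricted mean
  survival, linear tail extension floored at zero.
* **Evaluation** — Harrell concordance, Hosmer–Lemeshow-style
  1-calibration at the 10/25/50/75/90th event-time percentiles,
  D-calibration with conditional-uniform censored mass, IPCW integrated
  Brier score, all under stratified 5-fold cross-validation.
* **Interpretation** — per-time covariate weight profiles pooled across
  folds, mean weights with 1000-resample bootstrap CIs, one-sample
  Wilcoxon tests with Benjamini–Hochberg correction, correlation with
  full-data Cox coefficients, and counterfactual curve pairs.
* **Synthetic cohorts** — a piecewise-exponential generator with
  time-varying effects (chemotherapy protective early then null, stage IV
  constantly harmful, a tumour-microenvironment score strongest late),
  realistic covariate marginals and ~50% censoring, plus closed-form true
  survival for oracle testing.

## A worked example

```r
library(isdkit)

sim <- generate_cohort(synthetic_config(n = 1043), seed = 1)
report <- cross_validated_evaluation(
  sim$cohort, models = c("mtlr", "coxkp", "coxen", "aft"), k = 5, seed = 2
)
glance(report)[, 1:6]
#> # A tibble: 4 × 6
#>   model concordance_mean concordance_sd ibs_mean  ibs_sd d_cal_p
#>   <chr>            <dbl>          <dbl>    <dbl>   <dbl>   <dbl>
#> 1 aft              0.621         0.0382    0.195 0.00652   0.337
#> 2 coxen            0.621         0.0363    0.194 0.00658   0.851
#> 3 coxkp            0.621         0.0391    0.194 0.00676   0.913
#> 4 mtlr             0.615         0.0363    0.194 0.00553   0.813
```

All four models discriminate almost identically on this cohort
(concordance ≈ 0.62 with the default moderate effect sizes) and all are
D-calibrated (p ≫ 0.05) — the point of ISD evaluation is that
discrimination alone does not separate them; calibration and the
interpretation layer do.

```r
fit <- fit_mtlr(sim$cohort, seed = 2)
patient <- sim$cohort[sim$cohort$treatment == "No" &
                      sim$cohort$stage == "IV", ][1, ]
pair <- counterfactual_curves(fit, patient, toggle = list(treatment = "Yes"))
pair$summary
#> # A tibble: 2 × 4
#>   time_months surv_factual surv_counterfactual difference
#>         <dbl>        <dbl>               <dbl>      <dbl>
#> 1          24        0.439               0.618      0.179
#> 2          48        0.273               0.396      0.123
```

For this untreated stage-IV patient the model predicts a 17.9-point higher
survival probability at 24 months (12.3 at 48) had they received
chemotherapy — the generator's protective-early treatment effect, read back
from the fitted curves. (A prediction contrast, not a causal estimate.)

Weight interpretation:

```r
folds <- stratified_kfold_split(sim$cohort, k = 5, seed = 2)
fits <- lapply(folds, function(f) fit_mtlr(sim$cohort[f$train, ], seed = 2))
prof <- collect_out_of_fold_weights(fits)
autoplot(prof)                      # loess-smoothed time profiles, top 5
ws <- weight_summary(prof, n_boot = 1000, seed = 3)
autoplot(ws)                        # forest plot with bootstrap CIs
correlate_with_cox(ws, fit_cox(sim$cohort))$pearson_r
#> [1] 0.924926
```

## Command-line pipeline

A thin Rscript wrapper chains the stages:

```sh
Rscript inst/cli/isdkit.R simulate  --out run --n 1000 --seed 1
Rscript inst/cli/isdkit.R evaluate  --out run
Rscript inst/cli/isdkit.R interpret --out run
Rscript inst/cli/isdkit.R predict   --model run/mtlr_model.json \
    --patient patient.csv --times 24,48 --toggle treatment=Yes
```

Outputs are plain CSV/JSON (cohort, ground truth, a models-by-metrics
table, weight profiles, forest-plot data, correlation scatter, serialized
models); all seeds are persisted in `run_config.yaml`, and re-runs are
byte-identical.

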