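#' Run configuration for the end-to-end pipeline
#'
#' Collects every setting (and, crucially, every seed) a full analysis run
#' needs, so re-runs are exactly reproducible. Persisted alongside the
#' outputs of each `cmd_*` stage.
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param models Models to evaluate (see [cross_validated_evaluation()]).
#' @param k Outer CV folds.
#' @param sim_seed,cv_seed,boot_seed Seeds for simulation, CV split and
#'   bootstrap.
#' @param n_boot Bootstrap resamples for the interpretation stage.
#' @param lambda_grid MTLR penalty grid for inner CV.
#' @param sim Optional list of [synthetic_config()] overrides (e.g. `n`).
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, models = c("mtlr", "coxkp", "coxen", "aft"),
                       k = 5, sim_seed = 1, cv_seed = 2, boot_seed = 3,
                       n_boot = 1000, lambda_grid = 4^(-3:3),
                       sim = list(), out_dir = ".") {
  known_sim <- names(formals(synthetic_config))
  bad <- setdiff(names(sim), known_sim)
  if (length(bad)) abort(paste0("unknown simulate config key(s): ", paste(bad, collapse = ", ")))
  structure(
    list(input = input, models = models, k = k, sim_seed = sim_seed,
         cv_seed = cv_seed, boot_seed = boot_seed, n_boot = n_boot,
         lambda_grid = lambda_grid, sim = sim, out_dir = out_dir),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#' @param path YAML file with keys matching [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(run_config)))
  if (length(bad)) abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  do.call(run_config, raw)
}

persist_config <- function(config, out_dir) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$sim <- if (length(cfg$sim)) cfg$sim else NULL
  yaml::write_yaml(cfg, file.path(out_dir, "run_config.yaml"))
}

log_stage <- function(...) message(sprintf(...))

#' Simulate a cohort and write cohort + ground-truth CSVs
#'
#' @param config A [run_config()].
#' @return Invisibly, list of written paths.
#' @export
cmd_simulate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- do.call(synthetic_config, config$sim)
  sim <- generate_cohort(sc, seed = config$sim_seed)
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  truth_path <- file.path(config$out_dir, "truth.csv")
  write_cohort_csv(sim$cohort, cohort_path)
  readr::write_csv(sim$truth, truth_path, progress = FALSE)
  persist_config(config, config$out_dir)
  log_stage("simulate: n=%d events=%d censored=%.1f%%",
            nrow(sim$cohort), sum(sim$cohort$event),
            100 * attr(sim$truth, "censoring_fraction"))
  invisible(list(cohort = cohort_path, truth = truth_path))
}

load_pipeline_cohort <- function(config) {
  path <- config$input %||% file.path(config$out_dir, "cohort.csv")
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  read_cohort_csv(path, gastric_schema())
}

#' Cross-validated evaluation stage
#'
#' Fits and evaluates the configured models under k-fold CV and writes
#' `report.json` plus a models-by-metrics `metrics_table.csv`.
#'
#' @param config A [run_config()].
#' @return The `isd_evaluation`, invisibly.
#' @export
cmd_evaluate <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_pipeline_cohort(config)
  report <- cross_validated_evaluation(
    cohort, models = config$models, k = config$k, seed = config$cv_seed,
    model_opts = list(mtlr = list(lambda_grid = config$lambda_grid))
  )
  write_evaluation_report(
    report,
    json_path = file.path(config$out_dir, "report.json"),
    csv_path = file.path(config$out_dir, "metrics_table.csv")
  )
  persist_config(config, config$out_dir)
  log_stage("evaluate: n=%d events=%d k=%d models=%s",
            nrow(cohort), sum(cohort$event), config$k,
            paste(report$summary$model, collapse = ","))
  invisible(report)
}

#' Interpretation stage: weight profiles, forest data, Cox correlation
#'
#' Re-runs the MTLR CV fits on the configured cohort, then writes
#' `weight_profiles.csv` (covariate, fold, tau, weight), `forest_plot.csv`
#' (mean, bootstrap CI, raw/adjusted p), and `cox_correlation.csv`
#' (per-covariate MTLR weight vs full-data Cox coefficient, with r and p in
#' `cox_correlation.json`). The fitted full-cohort MTLR model is serialized
#' to `mtlr_model.json` for [cmd_predict()].
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the profile, summary and correlation.
#' @export
cmd_interpret <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- load_pipeline_cohort(config)
  folds <- stratified_kfold_split(cohort, k = config$k, seed = config$cv_seed)
  fits <- lapply(seq_along(folds), function(f) {
    tr <- folds[[f]]$train
    train <- cohort[tr, ]
    attr(train, "schema") <- attr(cohort, "schema")
    class(train) <- class(cohort)
    fit_mtlr(train, lambda_grid = config$lambda_grid,
             seed = config$cv_seed + 1000L * f)
  })
  profile <- collect_out_of_fold_weights(fits)
  summary <- weight_summary(profile, n_boot = config$n_boot, seed = config$boot_seed)
  cox_full <- fit_cox(cohort)
  corr <- correlate_with_cox(summary, cox_full)

  readr::write_csv(tibble::as_tibble(profile),
                   file.path(config$out_dir, "weight_profiles.csv"), progress = FALSE)
  readr::write_csv(tibble::as_tibble(summary),
                   file.path(config$out_dir, "forest_plot.csv"), progress = FALSE)
  readr::write_csv(corr$data,
                   file.path(config$out_dir, "cox_correlation.csv"), progress = FALSE)
  jsonlite::write_json(list(pearson_r = corr$pearson_r, p_value = corr$p_value),
                       file.path(config$out_dir, "cox_correlation.json"),
                       auto_unbox = TRUE, digits = NA)
  full_fit <- fit_mtlr(cohort, lambda_grid = config$lambda_grid, seed = config$cv_seed)
  write_model_json(full_fit, file.path(config$out_dir, "mtlr_model.json"))
  persist_config(config, config$out_dir)
  log_stage("interpret: folds=%d covariates=%d boot=%d pearson_r=%.3f",
            length(fits), length(unique(profile$covariate)), config$n_boot,
            corr$pearson_r)
  invisible(list(profile = profile, summary = summary, correlation = corr,
                 model = full_fit))
}

#' Predict an individual survival distribution from a serialized model
#'
#' Reads a model JSON ([write_model_json()]) and a one-row patient CSV,
#' writes the predicted curve as CSV and returns median survival plus
#' survival probabilities at requested times; `toggle` produces a
#' counterfactual pair instead.
#'
#' @param model_path Path to a model JSON.
#' @param patient Either a one-row data frame or a path to a one-row CSV of
#'   raw covariates.
#' @param times Query times (months).
#' @param toggle Optional named list for a counterfactual contrast.
#' @param out_dir Output directory (default: no files written).
#' @return A list with `curve` (and `counterfactual` if toggled), `median`,
#'   and a tibble `at_times`.
#' @export
cmd_predict <- function(model_path, patient, times = c(24, 48), toggle = NULL,
                        out_dir = NULL) {
  model <- read_model_json(model_path)
  if (is.character(patient)) {
    patient <- readr::read_csv(patient, show_col_types = FALSE, progress = FALSE)
  }
  if (nrow(patient) != 1) abort("predict expects exactly one patient row")
  curve <- predict_survival_curve(model, patient)
  out <- list(
    curve = curve,
    median = median_survival_time(curve),
    at_times = tibble::tibble(time_months = times,
                              survival_prob = survival_at_time(curve, times))
  )
  if (!is.null(toggle)) {
    pair <- counterfactual_curves(model, patient, toggle, times = times)
    out$counterfactual <- pair
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_curve_csv(curve, file.path(out_dir, "predicted_curve.csv"))
    readr::write_csv(out$at_times, file.path(out_dir, "survival_at_times.csv"),
                     progress = FALSE)
    if (!is.null(toggle)) {
      write_curve_csv(out$counterfactual$counterfactual,
                      file.path(out_dir, "counterfactual_curve.csv"))
      readr::write_csv(out$counterfactual$summary,
                       file.path(out_dir, "counterfactual_summary.csv"),
                       progress = FALSE)
    }
  }
  out
}
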