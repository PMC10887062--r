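#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risk ordering agrees
#' with the observed survival ordering. Comparable pairs are (i, j) with
#' `t_i < t_j` and patient i uncensored; tied risks receive half credit.
#' The convention throughout the package is risk = negative predicted median
#' survival time (higher risk, earlier predicted death).
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @param times,events Observed times and event indicators.
#' @return Concordance in [0, 1].
#' @export
concordance_index <- function(risk, times, events) {
  n <- length(risk)
  stopifnot(length(times) == n, length(events) == n)
  conc <- 0; ties <- 0; comparable <- 0
  for (i in which(events == 1)) {
    later <- which(times > times[i])
    if (!length(later)) next
    comparable <- comparable + length(later)
    conc <- conc + sum(risk[i] > risk[later])
    ties <- ties + sum(risk[i] == risk[later])
  }
  if (comparable == 0) abort("no comparable pairs: concordance undefined")
  (conc + 0.5 * ties) / comparable
}

km_survival_at <- function(times, events, t_star) {
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  s <- summary(fit, times = t_star, extend = TRUE)$surv
  if (!length(s)) 1 else s
}

#' 1-calibration (Hosmer-Lemeshow test at a single time point)
#'
#' Sorts patients into groups by predicted event probability
#' `1 - S_i(t_star)`, estimates each group's observed event rate at `t_star`
#' by a within-group Kaplan-Meier (censoring-adjusted), and refers
#' \eqn{\sum_g n_g (O_g - E_g)^2 / (E_g (1 - E_g))} to a chi-squared
#' distribution with `n_groups - 2` degrees of freedom. Groups with a
#' degenerate expected rate (0 or 1) are merged with a neighbour.
#'
#' @param curves List of [survival_curve()]s, one per patient.
#' @param times,events Observed times and event indicators.
#' @param t_star Evaluation time (> 0).
#' @param n_groups Number of risk groups (default 10 deciles).
#' @return List: `statistic`, `p_value`, `df`, and the per-group table.
#' @export
one_calibration <- function(curves, times, events, t_star, n_groups = 10) {
  stopifnot(t_star > 0)
  pred <- 1 - vapply(curves, survival_at_time, numeric(1), t = t_star)
  n <- length(pred)
  ord <- order(pred)
  grp <- integer(n)
  grp[ord] <- ceiling(seq_len(n) / (n / n_groups))
  grp <- pmin(grp, n_groups)

  groups <- lapply(sort(unique(grp)), function(g) list(members = g))
  summarise_groups <- function(groups) {
    purrr::map_dfr(groups, function(g) {
      idx <- which(grp %in% g$members)
      tibble::tibble(
        n_g = length(idx),
        expected = mean(pred[idx]),
        observed = 1 - km_survival_at(times[idx], events[idx], t_star)
      )
    })
  }
  tab <- summarise_groups(groups)
  # merge groups whose expected rate is degenerate into their neighbour
  while (length(groups) > 2 && any(tab$expected <= 0 | tab$expected >= 1)) {
    i <- which(tab$expected <= 0 | tab$expected >= 1)[1]
    j <- if (i == 1) 2 else i - 1
    groups[[j]]$members <- c(groups[[j]]$members, groups[[i]]$members)
    groups <- groups[-i]
    tab <- summarise_groups(groups)
  }
  stat <- with(tab, sum(n_g * (observed - expected)^2 / (expected * (1 - expected))))
  df <- max(1, nrow(tab) - 2)
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
       df = df, groups = tab)
}

#' D-calibration (distribution calibration)
#'
#' If predicted curves are correct, the predicted survival probability
#' evaluated at each patient's event time is Uniform(0, 1). Each uncensored
#' patient contributes mass 1 to the decile containing `S_i(t_i)`; a
#' censored patient with `p = S_i(c_i) > 0` spreads conditional-uniform
#' fractional mass `(min(b_hi, p) - b_lo)+ / p` over the bins below `p`
#' (a censored patient with `p = 0` is assigned to the lowest bin). The bin
#' masses are tested against uniformity by Pearson's chi-squared with
#' `n_bins - 1` degrees of freedom.
#'
#' @param curves List of [survival_curve()]s.
#' @param times,events Observed times and event indicators.
#' @param n_bins Number of probability bins (default 10).
#' @return List: `statistic`, `p_value`, `df`, `bin_masses`.
#' @export
d_calibration <- function(curves, times, events, n_bins = 10) {
  n <- length(curves)
  s_obs <- vapply(seq_len(n), function(i) survival_at_time(curves[[i]], times[i]),
                  numeric(1))
  edges <- seq(0, 1, length.out = n_bins + 1)
  masses <- numeric(n_bins)
  for (i in seq_len(n)) {
    p <- s_obs[i]
    if (events[i] == 1) {
      bin <- min(n_bins, findInterval(p, edges, rightmost.closed = TRUE))
      bin <- max(1L, bin)
      masses[bin] <- masses[bin] + 1
    } else if (p <= 0) {
      masses[1] <- masses[1] + 1
    } else {
      lo <- edges[-length(edges)]; hi <- edges[-1]
      masses <- masses + pmax(0, pmin(hi, p) - lo) / p
    }
  }
  expected <- n / n_bins
  stat <- sum((masses - expected)^2 / expected)
  list(statistic = stat,
       p_value = pchisq(stat, n_bins - 1, lower.tail = FALSE),
       df = n_bins - 1, bin_masses = masses)
}

censor_km_lookup <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  kt <- fit$time; ks <- fit$surv
  function(t, left = FALSE) {
    vapply(t, function(x) {
      idx <- if (left) which(kt < x) else which(kt <= x)
      if (!length(idx)) 1 else ks[max(idx)]
    }, numeric(1))
  }
}

#' Integrated Brier score with IPCW censoring adjustment
#'
#' Time-dependent Brier score
#' \deqn{BS(t) = n^{-1} \sum_i S_i(t)^2 \frac{1(t_i \le t,\,\delta_i = 1)}{G(t_i^-)}
#'   + (1 - S_i(t))^2 \frac{1(t_i > t)}{G(t)}}
#' with G the Kaplan-Meier estimate of the censoring distribution,
#' integrated over [0, `t_max`] by the trapezoid rule on the pooled
#' event-time grid and normalized by `t_max`. Integration truncates at the
#' last time where G > 0.
#'
#' @param curves List of [survival_curve()]s.
#' @param times,events Observed times and event indicators.
#' @param t_max Upper limit of integration (months).
#' @return Integrated Brier score (>= 0).
#' @export
integrated_brier <- function(curves, times, events, t_max = max(times[events == 1])) {
  n <- length(curves)
  G <- censor_km_lookup(times, events)
  grid <- sort(unique(c(0, times[events == 1 & times <= t_max], t_max)))
  usable <- G(grid) > 0
  if (!all(usable)) grid <- grid[seq_len(max(which(usable)))]
  Smat <- vapply(curves, function(cv) survival_at_time(cv, grid), numeric(length(grid)))
  if (length(grid) == 1) Smat <- matrix(Smat, nrow = 1)
  g_tminus <- G(times, left = TRUE)
  g_grid <- G(grid)
  bs <- vapply(seq_along(grid), function(j) {
    t <- grid[j]
    died <- times <= t & events == 1
    alive <- times > t
    terms <- numeric(n)
    terms[died] <- Smat[j, died]^2 / g_tminus[died]
    terms[alive] <- (1 - Smat[j, alive])^2 / g_grid[j]
    mean(terms)
  }, numeric(1))
  sum(diff(grid) * (head(bs, -1) + tail(bs, -1)) / 2) / t_max
}

model_fitters <- function() {
  list(
    mtlr = function(train, opts) {
      fit_mtlr(train,
               lambda = opts[["lambda"]] %||% NULL,
               lambda_grid = opts[["lambda_grid"]] %||% 4^(-3:3),
               inner_k = opts[["inner_k"]] %||% 5,
               seed = opts[["fold_seed"]])
    },
    coxkp = function(train, opts) fit_cox(train),
    coxen = function(train, opts) {
      fit_coxen(train,
                alpha_en = opts[["alpha_en"]] %||% NULL,
                l1_ratio = opts[["l1_ratio"]] %||% 0.5,
                inner_k = opts[["inner_k"]] %||% 5,
                seed = opts[["fold_seed"]])
    },
    aft = function(train, opts) fit_weibull_aft(train)
  )
}

risk_from_curve <- function(curve, use_mean = FALSE, horizon = NULL) {
  if (use_mean) return(-restricted_mean_survival(curve, horizon %||% max(curve$times)))
  med <- median_survival_time(curve)
  if (is.na(med)) med <- Inf
  -med
}

#' Cross-validated evaluation of ISD models
#'
#' Runs stratified k-fold cross-validation: each model is fitted on the
#' training folds (including any internal hyperparameter selection) and
#' predicts ISDs for its test fold. Concordance and integrated Brier are
#' computed per fold and summarized mean +/- sd; D-calibration and
#' 1-calibration are computed once on the pooled out-of-fold predictions,
#' the latter at the 10/25/50/75/90th percentiles of observed (uncensored)
#' event times.
#'
#' @param cohort A `cohort_table`.
#' @param models Character vector from `"mtlr"`, `"coxkp"`, `"coxen"`,
#'   `"aft"`, and/or named [isd_adapter()] objects.
#' @param k Folds (default 5).
#' @param seed Seed for the CV split (inner selections derive from it).
#' @param model_opts Named list of per-model option lists (e.g.
#'   `list(mtlr = list(lambda = 1))`).
#' @param risk Risk convention, `"median"` (negative predicted median,
#'   default) or `"mean"` (negative restricted mean survival).
#' @return An `isd_evaluation` object; see [glance.isd_evaluation()].
#' @export
cross_validated_evaluation <- function(cohort, models = c("mtlr", "coxkp", "coxen", "aft"),
                                       k = 5, seed = 1, model_opts = list(),
                                       risk = c("median", "mean")) {
  risk <- match.arg(risk)
  if (sum(cohort$event) == 0) abort("cohort has zero events: nothing to evaluate")
  folds <- stratified_kfold_split(cohort, k = k, seed = seed)
  bad <- vapply(folds, function(f) sum(cohort$event[f$train]) == 0 ||
                  sum(cohort$event[f$test]) == 0, logical(1))
  if (any(bad)) abort("a fold has no events; use stratification or more data")
  fitters <- model_fitters()

  adapters <- models[vapply(models, inherits, logical(1), "isd_adapter")]
  model_names <- vapply(models, function(mm) {
    if (inherits(mm, "isd_adapter")) mm$label else as.character(mm)
  }, character(1))
  ev_times <- cohort$time_months[cohort$event == 1]
  anchors <- quantile(ev_times, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7)

  per_fold <- list(); pooled <- list(); fold_models <- list()
  for (mi in seq_along(models)) {
    mm <- models[[mi]]; nm <- model_names[mi]
    c_idx <- numeric(k); ibs <- numeric(k)
    oof_curves <- vector("list", nrow(cohort))
    fits <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- folds[[f]]$train; te <- folds[[f]]$test
      train <- cohort[tr, ]; test <- cohort[te, ]
      attr(train, "schema") <- attr(cohort, "schema")
      attr(test, "schema") <- attr(cohort, "schema")
      class(train) <- class(cohort); class(test) <- class(cohort)
      fit <- if (inherits(mm, "isd_adapter")) mm else {
        opts <- model_opts[[nm]] %||% list()
        opts$fold_seed <- seed + 1000L * f
        fitters[[nm]](train, opts)
      }
      curves <- predict_survival_curve(fit, test)
      if (inherits(curves, "survival_curve")) curves <- list(curves)
      risks <- vapply(curves, risk_from_curve, numeric(1),
                      use_mean = (risk == "mean"))
      c_idx[f] <- concordance_index(risks, test$time_months, test$event)
      ibs[f] <- integrated_brier(curves, test$time_months, test$event)
      oof_curves[te] <- curves
      fits[[f]] <- fit
    }
    dcal <- d_calibration(oof_curves, cohort$time_months, cohort$event)
    ocal <- lapply(anchors, function(a)
      one_calibration(oof_curves, cohort$time_months, cohort$event, a))
    per_fold[[nm]] <- tibble::tibble(model = nm, fold = seq_len(k),
                                     concordance = c_idx, ibs = ibs)
    pooled[[nm]] <- list(d_calibration = dcal, one_calibration = ocal,
                         curves = oof_curves)
    fold_models[[nm]] <- fits
  }

  summary <- dplyr::bind_rows(per_fold) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      concordance_mean = mean(.data$concordance),
      concordance_sd = sd(.data$concordance),
      ibs_mean = mean(.data$ibs),
      ibs_sd = sd(.data$ibs),
      .groups = "drop"
    )
  summary$d_cal_p <- vapply(summary$model, function(nm)
    pooled[[nm]]$d_calibration$p_value, numeric(1))
  for (qi in seq_along(anchors)) {
    summary[[paste0("one_cal_p", c(10, 25, 50, 75, 90)[qi])]] <-
      vapply(summary$model, function(nm)
        pooled[[nm]]$one_calibration[[qi]]$p_value, numeric(1))
  }
  structure(
    list(summary = summary, per_fold = dplyr::bind_rows(per_fold),
         pooled = pooled, anchors = anchors, k = k, seed = seed,
         folds = folds, fold_models = fold_models, risk = risk),
    class = "isd_evaluation"
  )
}

#' @export
print.isd_evaluation <- function(x, ...) {
  cat("<isd_evaluation> ", x$k, "-fold CV, models: ",
      paste(x$summary$model, collapse = ", "), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' One row per model with all evaluation metrics
#' @param x An `isd_evaluation`.
#' @param ... Unused.
#' @return A tibble, models by metrics.
#' @method glance isd_evaluation
#' @export
glance.isd_evaluation <- function(x, ...) x$summary

#' Long per-fold metric table
#' @param x An `isd_evaluation`.
#' @param ... Unused.
#' @return Tibble with `model`, `fold`, `concordance`, `ibs`.
#' @method tidy isd_evaluation
#' @export
tidy.isd_evaluation <- function(x, ...) x$per_fold

#' Write an evaluation report as JSON and a models-by-metrics CSV
#'
#' @param report An `isd_evaluation`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary tibble.
#' @export
write_evaluation_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "isd_evaluation"))
  if (!is.null(json_path)) {
    payload <- list(
      k = report$k, seed = report$seed,
      anchors_months = as.numeric(report$anchors),
      summary = report$summary, per_fold = report$per_fold
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    # models-by-metrics table: mean +/- sd cells for concordance and IBS,
    # p-value cells for the calibration rows
    fmt <- function(m, s) sprintf("%.3f ± %.3f", m, s)
    long <- report$summary |>
      dplyr::transmute(
        model = .data$model,
        Concordance = fmt(.data$concordance_mean, .data$concordance_sd),
        `D-Calibration` = sprintf("%.3f", .data$d_cal_p),
        `1-Calibration 10th` = sprintf("%.3f", .data$one_cal_p10),
        `1-Calibration 25th` = sprintf("%.3f", .data$one_cal_p25),
        `1-Calibration 50th` = sprintf("%.3f", .data$one_cal_p50),
        `1-Calibration 75th` = sprintf("%.3f", .data$one_cal_p75),
        `1-Calibration 90th` = sprintf("%.3f", .data$one_cal_p90),
        `Integrated Brier` = fmt(.data$ibs_mean, .data$ibs_sd)
      ) |>
      tidyr::pivot_longer(-"model", names_to = "Metric", values_to = "value") |>
      tidyr::pivot_wider(names_from = "model", values_from = "value")
    readr::write_csv(long, csv_path, progress = FALSE)
  }
  invisible(report$summary)
}

#' Read back a JSON evaluation report
#' @param json_path Path written by [write_evaluation_report()].
#' @return List with `k`, `seed`, `anchors_months`, `summary`, `per_fold`.
#' @export
read_evaluation_report <- function(json_path) {
  pl <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  pl$summary <- tibble::as_tibble(pl$summary)
  pl$per_fold <- tibble::as_tibble(pl$per_fold)
  pl
}
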