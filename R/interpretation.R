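#' Collect per-time MTLR weights across cross-validation folds
#'
#' Pools the fitted weight matrices of k cross-validation MTLR models (each
#' trained on a different subset, so the k profiles describe the
#' out-of-fold generalisation of each covariate effect) into a long
#' `(covariate, fold, tau, weight)` table. Weights are on the
#' standardized-covariate scale recorded in each fit's design metadata.
#' Folds with different time grids are pooled as `(tau, weight)` pairs, not
#' aligned by index.
#'
#' @param cv_fits List of `mtlr_fit` objects sharing one covariate schema
#'   (e.g. `fold_models$mtlr` from [cross_validated_evaluation()]).
#' @return A `time_profile` tibble with columns `covariate`, `fold`, `tau`,
#'   `weight`.
#' @export
collect_out_of_fold_weights <- function(cv_fits) {
  if (length(cv_fits) < 2) abort("need at least 2 fold models")
  cols <- lapply(cv_fits, function(f) f$design$columns)
  if (!all(vapply(cols, identical, logical(1), cols[[1]]))) {
    abort("fold models do not share a covariate schema")
  }
  out <- purrr::imap_dfr(cv_fits, function(fit, f) {
    tidy(fit) |>
      dplyr::transmute(covariate = .data$term, fold = as.integer(f),
                       tau = .data$tau, weight = .data$weight)
  })
  structure(out, class = c("time_profile", class(tibble::tibble())))
}

#' Rank covariates by influence
#'
#' Influence is the absolute value of the mean weight over all time points
#' and folds, sorted descending; ties break alphabetically.
#'
#' @param profiles A `time_profile`.
#' @return Character vector of covariates, most influential first.
#' @export
rank_influential <- function(profiles) {
  means <- profiles |>
    dplyr::group_by(.data$covariate) |>
    dplyr::summarise(mean_weight = mean(.data$weight), .groups = "drop")
  means$covariate[order(-abs(means$mean_weight), means$covariate)]
}

#' Percentile bootstrap CI for a mean weight
#'
#' Resamples the pooled individual `(fold, tau)` weight values with
#' replacement `n_boot` times and returns the 2.5/97.5 percentile interval
#' of the resampled means.
#'
#' @param values Numeric vector of weight values (>= 2).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Named vector `c(mean, lo, hi)`.
#' @export
bootstrap_mean_weight_ci <- function(values, n_boot = 1000, seed = 1) {
  if (length(values) < 2) abort("need at least 2 weight values")
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    mean(sample(values, replace = TRUE)), numeric(1))
  ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
  c(mean = mean(values), lo = ci[1], hi = ci[2])
}

#' Per-covariate significance of mean weights
#'
#' One-sample test of each covariate's pooled weight values against zero
#' (Wilcoxon signed-rank by default; one-sample t-test behind `test = "t"`),
#' with Benjamini-Hochberg adjustment across covariates. A covariate whose
#' weights are all exactly zero gets p = 1 by convention.
#'
#' @param profiles A `time_profile`.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return Tibble with `covariate`, `p_value`, `p_adjusted`.
#' @export
weight_significance <- function(profiles, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  res <- profiles |>
    dplyr::group_by(.data$covariate) |>
    dplyr::summarise(
      p_value = {
        v <- .data$weight
        if (all(v == 0)) 1 else if (test == "wilcoxon") {
          wilcox.test(v, mu = 0, exact = NULL)$p.value
        } else {
          t.test(v, mu = 0)$p.value
        }
      },
      .groups = "drop"
    )
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res
}

#' Forest-plot summary of covariate weights
#'
#' Per covariate: mean weight over all time points and folds, 1000-bootstrap
#' percentile 95\% CI, raw and BH-adjusted one-sample test p-values, and
#' influence rank. The standard interpretation display of a cross-validated
#' MTLR fit: negative weights favour survival.
#'
#' @param profiles A `time_profile` from [collect_out_of_fold_weights()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param test Significance test, `"wilcoxon"` (default) or `"t"`.
#' @param by_fold Resample whole folds instead of individual weight values
#'   (default `FALSE`).
#' @return A `weight_summary` tibble: `covariate`, `mean_weight`, `ci_lo`,
#'   `ci_hi`, `p_value`, `p_adjusted`, `rank`.
#' @export
weight_summary <- function(profiles, n_boot = 1000, seed = 1,
                           test = c("wilcoxon", "t"), by_fold = FALSE) {
  test <- match.arg(test)
  covs <- sort(unique(profiles$covariate))
  rows <- purrr::imap_dfr(setNames(covs, covs), function(cv, nm) {
    v <- profiles$weight[profiles$covariate == cv]
    est <- if (by_fold) {
      folds <- unique(profiles$fold[profiles$covariate == cv])
      set.seed(seed)
      boots <- vapply(seq_len(n_boot), function(i) {
        fs <- sample(folds, replace = TRUE)
        mean(unlist(lapply(fs, function(f)
          profiles$weight[profiles$covariate == cv & profiles$fold == f])))
      }, numeric(1))
      ci <- unname(quantile(boots, c(0.025, 0.975), type = 7))
      c(mean = mean(v), lo = ci[1], hi = ci[2])
    } else {
      bootstrap_mean_weight_ci(v, n_boot = n_boot, seed = seed)
    }
    tibble::tibble(covariate = cv, mean_weight = est["mean"],
                   ci_lo = est["lo"], ci_hi = est["hi"])
  })
  sig <- weight_significance(profiles, test = test)
  out <- dplyr::left_join(rows, sig, by = "covariate")
  ranking <- rank_influential(profiles)
  out$rank <- match(out$covariate, ranking)
  out <- dplyr::arrange(out, .data$rank)
  structure(out, class = c("weight_summary", class(tibble::tibble())))
}

#' Correlate MTLR mean weights with full-data Cox coefficients
#'
#' Pearson correlation (with the usual t-distributed p-value) between the
#' fold-averaged MTLR weight and the coefficient of a Cox model fitted once
#' on the full cohort, matched by encoded covariate. The scatter data is
#' returned for plotting.
#'
#' @param summary A `weight_summary`.
#' @param cox_fit A `cox_isd` fitted on the full data.
#' @return List: `pearson_r`, `p_value`, `data` (tibble of matched pairs).
#' @export
correlate_with_cox <- function(summary, cox_fit) {
  stopifnot(inherits(cox_fit, "cox_isd"))
  common <- intersect(summary$covariate, names(cox_fit$beta))
  if (length(common) < 3) abort("need at least 3 shared covariates")
  df <- tibble::tibble(
    covariate = common,
    mtlr_weight = summary$mean_weight[match(common, summary$covariate)],
    cox_coef = as.numeric(cox_fit$beta[common])
  )
  ct <- cor.test(df$mtlr_weight, df$cox_coef, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value, data = df)
}

#' Counterfactual survival-curve pair for one patient
#'
#' Predicts the patient's ISD under their observed covariates and under the
#' same covariates with one or more inputs toggled (e.g. chemotherapy
#' yes/no), and summarizes the survival differences at query times together
#' with both medians. This is a model-prediction contrast under a changed
#' input, not a causal estimate.
#'
#' @param model A fitted ISD model with a `design` field.
#' @param patient One-row data frame of raw covariates.
#' @param toggle Named list of covariate = new value.
#' @param times Query times for the difference summary (months).
#' @return A `counterfactual_pair`: `factual`, `counterfactual` (curves),
#'   `summary` tibble (time, S under each, difference), `medians`.
#' @export
counterfactual_curves <- function(model, patient, toggle, times = c(24, 48)) {
  stopifnot(nrow(patient) == 1, length(toggle) >= 1)
  schema <- model$design$schema
  unknown <- setdiff(names(toggle), schema_covariates(schema))
  if (length(unknown)) {
    abort(paste0("toggle of unknown covariate(s): ", paste(unknown, collapse = ", ")))
  }
  cf_patient <- patient
  for (nm in names(toggle)) cf_patient[[nm]] <- toggle[[nm]]
  factual <- predict_survival_curve(model, patient)
  counterfactual <- predict_survival_curve(model, cf_patient)
  s_f <- survival_at_time(factual, times)
  s_c <- survival_at_time(counterfactual, times)
  structure(
    list(
      factual = factual, counterfactual = counterfactual,
      toggle = toggle,
      summary = tibble::tibble(
        time_months = times, surv_factual = s_f,
        surv_counterfactual = s_c, difference = s_c - s_f
      ),
      medians = c(factual = median_survival_time(factual),
                  counterfactual = median_survival_time(counterfactual))
    ),
    class = "counterfactual_pair"
  )
}

#' @export
print.counterfactual_pair <- function(x, ...) {
  cat("<counterfactual_pair> toggle:",
      paste(names(x$toggle), unlist(x$toggle), sep = " -> ", collapse = ", "), "\n")
  print(x$summary)
  cat("medians (months): factual =", format(x$medians["factual"]),
      ", counterfactual =", format(x$medians["counterfactual"]), "\n")
  invisible(x)
}

#' @method autoplot counterfactual_pair
#' @export
autoplot.counterfactual_pair <- function(object, ...) {
  autoplot(object$factual, counterfactual = object$counterfactual) +
    ggplot2::scale_colour_discrete(labels = c("factual", "counterfactual"))
}

#' Plot time-varying weight profiles (loess-smoothed)
#'
#' Raw per-fold weights are drawn as points with a local-regression smooth
#' (span 0.75) and pointwise 95\% band per covariate, for the `top_n` most
#' influential covariates.
#'
#' @param object A `time_profile`.
#' @param top_n Number of covariates to show (default 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot time_profile
#' @export
autoplot.time_profile <- function(object, top_n = 5, ...) {
  keep <- head(rank_influential(object), top_n)
  df <- dplyr::filter(object, .data$covariate %in% keep)
  ggplot2::ggplot(df, ggplot2::aes(.data$tau, .data$weight,
                                   colour = .data$covariate,
                                   fill = .data$covariate)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_smooth(method = "loess", span = 0.75, formula = y ~ x,
                         level = 0.95, linewidth = 0.8, alpha = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "Time (months)", y = "MTLR weight",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of mean weights with bootstrap CIs
#'
#' @param object A `weight_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot weight_summary
#' @export
autoplot.weight_summary <- function(object, ...) {
  df <- dplyr::mutate(object, covariate = factor(
    .data$covariate, levels = rev(object$covariate)))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_weight, .data$covariate)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.25) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_adjusted < 0.05)) +
    ggplot2::labs(x = "Mean MTLR weight (negative favours survival)",
                  y = NULL, colour = "BH p < 0.05") +
    ggplot2::theme_minimal()
}
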