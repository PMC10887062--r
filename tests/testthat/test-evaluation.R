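linear_curve_through <- function(s_at, t_at, t_end = 100) {
  # curve that passes S(t_at) = s_at by linear descent from 1 at 0
  survival_curve(c(0, t_at, t_end),
                 c(1, s_at, max(0, s_at - (1 - s_at) / t_at * (t_end - t_at))))
}

test_that("concordance matches pairwise enumeration on 3-patient fixtures", {
  times <- c(1, 2, 3); events <- c(1, 1, 0)
  expect_equal(concordance_index(c(3, 2, 1), times, events), 1)     # perfect
  expect_equal(concordance_index(c(2, 3, 1), times, events), 2 / 3) # one swap
  expect_equal(concordance_index(c(1, 1, 1), times, events), 0.5)   # all tied
  expect_error(concordance_index(c(1, 2), c(5, 5), c(0, 0)), "comparable")
})

test_that("concordance is invariant to strictly monotone risk transforms", {
  set.seed(4)
  n <- 120
  risk <- rnorm(n)
  times <- rexp(n, exp(0.5 * risk)); events <- rbinom(n, 1, 0.7)
  c1 <- concordance_index(risk, times, events)
  expect_equal(concordance_index(exp(risk), times, events), c1)
  expect_equal(concordance_index(rank(risk), times, events), c1)
})

test_that("concordance agrees with the survival package on untied data", {
  set.seed(5)
  n <- 150
  risk <- rnorm(n)
  times <- rexp(n, exp(0.8 * risk)); events <- rbinom(n, 1, 0.6)
  ours <- concordance_index(risk, times, events)
  ref <- survival::concordance(survival::Surv(times, events) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("1-calibration is exact when predictions equal observed group rates", {
  # two risk strata, no censoring, predictions equal to empirical rates
  t_star <- 10
  times <- c(rep(5, 2), rep(15, 8), rep(4, 7), rep(20, 3))
  events <- rep(1, 20)
  curves <- c(rep(list(linear_curve_through(0.8, t_star, 40)), 10),
              rep(list(linear_curve_through(0.3, t_star, 40)), 10))
  res <- one_calibration(curves, times, events, t_star, n_groups = 2)
  expect_lt(res$statistic, 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
})

test_that("1-calibration detects a systematic optimism shift", {
  set.seed(6)
  cohort <- make_simple_cohort(1500, list(x1 = 0.7), seed = 6)
  cfg <- attr(cohort, "config"); X <- attr(cohort, "X_raw")
  grid_t <- c(0, seq(2, 120, by = 2))
  truec <- lapply(seq_len(nrow(X)), function(i) {
    survival_curve(grid_t, true_survival_prob(X[i, , drop = FALSE], cfg, grid_t))
  })
  t_star <- median(cohort$time_months[cohort$event == 1])
  good <- one_calibration(truec, cohort$time_months, cohort$event, t_star)
  shifted <- lapply(truec, function(cv)
    survival_curve(cv$times, pmin(1, c(1, pmin(cv$probs[-1] + 0.15, 1)))))
  bad <- one_calibration(shifted, cohort$time_months, cohort$event, t_star)
  expect_gt(bad$statistic, good$statistic)
  expect_lt(bad$p_value, 0.05)
})

test_that("D-calibration hand values: concentrated vs uniform deciles", {
  # 10 uncensored patients whose S(t_i) lands one per decile
  s_vals <- seq(0.05, 0.95, by = 0.1)
  curves <- lapply(s_vals, function(s) linear_curve_through(s, 10))
  res <- d_calibration(curves, rep(10, 10), rep(1, 10))
  expect_equal(res$statistic, 0, tolerance = 1e-9)
  expect_equal(res$p_value, 1, tolerance = 1e-9)
  expect_equal(res$bin_masses, rep(1, 10), tolerance = 1e-9)

  # all mass in one decile: chi2 = 81 + 9 = 90 on df = 9
  curves2 <- rep(list(linear_curve_through(0.55, 10)), 10)
  res2 <- d_calibration(curves2, rep(10, 10), rep(1, 10))
  expect_equal(res2$statistic, 90, tolerance = 1e-9)
  expect_lt(res2$p_value, 1e-12)
})

test_that("censored patients spread conditional-uniform mass below S(c)", {
  cv <- linear_curve_through(0.35, 10)
  res <- d_calibration(list(cv), times = 10, events = 0)
  m <- res$bin_masses
  expect_equal(m[4], 0.05 / 0.35, tolerance = 1e-9)      # [0.3, 0.4)
  expect_equal(m[1:3], rep(0.1 / 0.35, 3), tolerance = 1e-9)
  expect_equal(sum(m), 1, tolerance = 1e-9)
})

test_that("D-calibration masses always sum to the cohort size", {
  set.seed(7)
  cohort <- make_simple_cohort(400, list(x1 = 0.5), seed = 7)
  fit <- fit_mtlr(cohort, lambda = 1)
  curves <- predict_survival_curve(fit, cohort)
  res <- d_calibration(curves, cohort$time_months, cohort$event)
  expect_equal(sum(res$bin_masses), nrow(cohort), tolerance = 1e-9)
})

test_that("integrated Brier scores perfect, constant and reference predictions", {
  # perfect prediction of a single death at t = 10
  perfect <- survival_curve(c(0, 9.999, 10), c(1, 1, 0))
  expect_lt(integrated_brier(list(perfect), 10, 1, t_max = 10), 1e-6)

  # near-constant 0.5 prediction over spread-out events: BS(t) ~ 0.25
  set.seed(8)
  n <- 60
  times <- sort(runif(n, 1, 50)); events <- rep(1, n)
  half <- survival_curve(c(0, 1e-6, 60), c(1, 0.5, 0.5))
  ibs_half <- integrated_brier(rep(list(half), n), times, events, t_max = 50)
  expect_equal(ibs_half, 0.25, tolerance = 0.02)

  # pooled KM beats the constant predictor on calibrated data
  cohort <- make_simple_cohort(1000, list(x1 = 0.6), seed = 8)
  km <- survival::survfit(survival::Surv(cohort$time_months, cohort$event) ~ 1)
  km_curve <- survival_curve(c(0, km$time[km$surv < 1]),
                             c(1, km$surv[km$surv < 1]))
  t_max <- quantile(cohort$time_months[cohort$event == 1], 0.9)
  ibs_km <- integrated_brier(rep(list(km_curve), nrow(cohort)),
                             cohort$time_months, cohort$event, t_max)
  ibs_flat <- integrated_brier(rep(list(survival_curve(c(0, 1e-6, 130), c(1, 0.5, 0.5))),
                                   nrow(cohort)),
                               cohort$time_months, cohort$event, t_max)
  expect_lt(ibs_km, ibs_flat)
})

test_that("cross-validated evaluation produces a complete, reproducible report", {
  cohort <- make_simple_cohort(300, list(x1 = 0.8, x2 = -0.5), seed = 9)
  rep1 <- cross_validated_evaluation(cohort, models = c("mtlr", "coxkp"),
                                     k = 3, seed = 4,
                                     model_opts = list(mtlr = list(lambda = 1)))
  expect_setequal(rep1$summary$model, c("mtlr", "coxkp"))
  expect_true(all(c("concordance_mean", "concordance_sd", "ibs_mean", "ibs_sd",
                    "d_cal_p", "one_cal_p10", "one_cal_p25", "one_cal_p50",
                    "one_cal_p75", "one_cal_p90") %in% names(rep1$summary)))
  expect_true(all(rep1$summary$concordance_mean >= 0 &
                    rep1$summary$concordance_mean <= 1))
  pcols <- grep("_p", names(rep1$summary), value = TRUE)
  expect_true(all(unlist(rep1$summary[pcols]) >= 0 &
                    unlist(rep1$summary[pcols]) <= 1))
  rep2 <- cross_validated_evaluation(cohort, models = c("mtlr", "coxkp"),
                                     k = 3, seed = 4,
                                     model_opts = list(mtlr = list(lambda = 1)))
  expect_equal(rep1$summary, rep2$summary, tolerance = 1e-10)
})

test_that("evaluation reports round-trip through JSON and CSV", {
  cohort <- make_simple_cohort(250, list(x1 = 0.8), seed = 10)
  rep1 <- cross_validated_evaluation(cohort, models = c("coxkp", "aft"),
                                     k = 3, seed = 2)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_evaluation_report(rep1, json_path = jp, csv_path = cp)
  back <- read_evaluation_report(jp)
  expect_equal(back$summary$concordance_mean, rep1$summary$concordance_mean,
               tolerance = 1e-12)
  expect_equal(back$k, rep1$k)
  tab <- readr::read_csv(cp, show_col_types = FALSE)
  expect_equal(nrow(tab), 8)   # concordance, D-cal, 5 x 1-cal, IBS
  expect_true(all(c("Metric", "coxkp", "aft") %in% names(tab)))
})

test_that("evaluation refuses cohorts without events", {
  df <- tibble::tibble(time_months = 1:10, event = 0, x = rnorm(10))
  cohort <- as_cohort(df, cohort_schema(continuous = "x"))
  expect_error(cross_validated_evaluation(cohort, models = "coxkp", k = 2),
               "zero events")
})
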