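# Shared fixture builders: everything is generated in code at test time.

# Low-dimensional cohort with continuous covariates and a piecewise-constant
# hazard; effects is a named list keyed by covariate name.
make_simple_cohort <- function(n, effects, seed = 1,
                               baseline = step_fn(c(0.03), 0),
                               censoring = list(horizon = 120, uniform_prob = 1,
                                                uniform_max = 120),
                               binary = character()) {
  set.seed(seed)
  covs <- names(effects)
  X <- vapply(covs, function(nm) {
    if (nm %in% binary) rbinom(n, 1, 0.5) else rnorm(n)
  }, numeric(n))
  colnames(X) <- covs
  cfg <- synthetic_config(n = n, baseline = baseline, effects = effects,
                          censoring = censoring)
  tt <- sample_event_time(X, cfg)
  cens <- apply_censoring(tt, cfg$censoring)
  df <- tibble::as_tibble(as.data.frame(X))
  df$time_months <- cens$observed
  df$event <- cens$event
  cohort <- as_cohort(df, cohort_schema(continuous = covs))
  attr(cohort, "true_times") <- tt
  attr(cohort, "X_raw") <- X
  attr(cohort, "config") <- cfg
  cohort
}

# tiny hand cohort for exact checks
make_toy_cohort <- function() {
  df <- tibble::tibble(
    time_months = c(1, 2, 3),
    event = c(1, 1, 1),
    x = c(0, 1, 0)
  )
  as_cohort(df, cohort_schema(continuous = "x"))
}

# brute-force MTLR negative log-likelihood by enumerating the m+1 monotone
# death-status sequences (independent of the package's vectorized path)
brute_mtlr_nll <- function(W, b, x, time, event, tau,
                           censored_inclusive = TRUE) {
  m <- length(tau)
  theta <- as.numeric(W %*% x + b)
  logu <- c(vapply(seq_len(m), function(k) sum(theta[k:m]), numeric(1)), 0)
  Z <- sum(exp(logu))
  if (event == 1) {
    k <- sum(tau < time) + 1
    -log(exp(logu[k]) / Z)
  } else {
    a <- sum(tau < time) + 1
    if (!censored_inclusive) a <- min(a + 1, m + 1)
    -log(sum(exp(logu[a:(m + 1)])) / Z)
  }
}

expect_curve_valid <- function(curve) {
  expect_s3_class(curve, "survival_curve")
  expect_equal(curve$times[1], 0)
  expect_equal(curve$probs[1], 1)
  expect_true(all(diff(curve$probs) <= 1e-12))
  expect_true(all(curve$probs >= 0 & curve$probs <= 1))
}
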