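test_that("time grid follows the square-root-of-events rule with quantile placement", {
  g1 <- build_time_grid(times = c(7.5, 3, 12), events = c(1, 0, 0))
  expect_equal(g1$m, 1)
  expect_equal(g1$tau, 7.5)

  times <- 1:100
  g2 <- build_time_grid(times, rep(1, 100))
  expect_equal(g2$m, 10)
  expect_equal(g2$tau,
               unname(quantile(1:100, probs = (1:10) / 11, type = 7)))

  g3 <- build_time_grid(rep(5, 9), rep(1, 9))
  expect_equal(g3$m, 1)   # ties collapse the grid
  expect_equal(g3$tau, 5)

  expect_error(build_time_grid(c(1, 2), c(0, 0)), "no uncensored")
})

test_that("objective matches hand-computable closed forms", {
  grid <- structure(list(tau = c(10, 20, 30, 40), m = 4L), class = "time_grid")
  W <- matrix(0, 4, 1); b <- rep(0, 4)
  # uncensored, zero params: uniform over m+1 sequences
  o <- mtlr_objective(W, b, matrix(1), times = 15, events = 1, grid)
  expect_equal(o$value, log(5), tolerance = 1e-12)

  # censored inside interval 2 of m = 2: mass {interval 2, interval 3} of 3
  grid2 <- structure(list(tau = c(10, 20), m = 2L), class = "time_grid")
  o2 <- mtlr_objective(matrix(0, 2, 1), rep(0, 2), matrix(1),
                       times = 15, events = 0, grid2)
  expect_equal(o2$value, -log(2 / 3), tolerance = 1e-12)

  # m=2, p=1, x=1, W=(0.5,-0.5), b=0, death in interval 1:
  # u1 = e^0, u2 = e^-0.5, u3 = 1
  o3 <- mtlr_objective(matrix(c(0.5, -0.5), 2, 1), rep(0, 2), matrix(1),
                       times = 5, events = 1, grid2)
  expect_equal(o3$value, -log(1 / (1 + exp(-0.5) + 1)), tolerance = 1e-12)
})

test_that("likelihood equals brute-force enumeration for m <= 8, censored and not", {
  set.seed(42)
  for (rep in 1:30) {
    m <- sample(1:8, 1); p <- sample(1:4, 1); n <- 6
    tau <- sort(runif(m, 1, 100))
    grid <- structure(list(tau = tau, m = m), class = "time_grid")
    X <- matrix(rnorm(n * p), n, p)
    W <- matrix(rnorm(m * p), m, p); b <- rnorm(m)
    times <- runif(n, 0.5, 110); events <- rbinom(n, 1, 0.5)
    for (inc in c(TRUE, FALSE)) {
      o <- mtlr_objective(W, b, X, times, events, grid, lambda = 0,
                          censored_inclusive = inc)
      bf <- sum(vapply(seq_len(n), function(i)
        brute_mtlr_nll(W, b, X[i, ], times[i], events[i], tau, inc), numeric(1)))
      expect_equal(o$value, bf, tolerance = 1e-10)
    }
  }
})

test_that("analytic gradient matches central finite differences", {
  set.seed(7)
  for (rep in 1:10) {
    m <- sample(2:6, 1); p <- sample(1:3, 1); n <- 8
    tau <- sort(runif(m, 1, 90))
    grid <- structure(list(tau = tau, m = m), class = "time_grid")
    X <- matrix(rnorm(n * p), n, p)
    times <- runif(n, 0.5, 100); events <- rbinom(n, 1, 0.6)
    W <- matrix(rnorm(m * p), m, p); b <- rnorm(m)
    lam <- runif(1, 0, 2)
    o <- mtlr_objective(W, b, X, times, events, grid, lambda = lam)
    an <- c(as.numeric(o$grad_W), o$grad_b)
    par <- c(as.numeric(W), b); eps <- 1e-6
    fd <- vapply(seq_along(par), function(j) {
      pp <- par; pp[j] <- pp[j] + eps
      pm <- par; pm[j] <- pm[j] - eps
      vp <- mtlr_objective(matrix(pp[1:(m * p)], m, p), pp[m * p + 1:m],
                           X, times, events, grid, lambda = lam)$value
      vm <- mtlr_objective(matrix(pm[1:(m * p)], m, p), pm[m * p + 1:m],
                           X, times, events, grid, lambda = lam)$value
      (vp - vm) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(an - fd) / pmax(1, abs(fd))), 1e-5)
  }
})

test_that("objective is numerically convex along random segments", {
  set.seed(13)
  m <- 4; p <- 2; n <- 30
  tau <- sort(runif(m, 2, 80))
  grid <- structure(list(tau = tau, m = m), class = "time_grid")
  X <- matrix(rnorm(n * p), n, p)
  times <- runif(n, 1, 100); events <- rbinom(n, 1, 0.5)
  val <- function(par) mtlr_objective(matrix(par[1:(m * p)], m, p),
                                      par[m * p + 1:m], X, times, events,
                                      grid, lambda = 0)$value
  npar <- m * p + m
  for (s in 1:100) {
    a <- rnorm(npar); bb <- rnorm(npar)
    expect_lte(val((a + bb) / 2), (val(a) + val(bb)) / 2 + 1e-9)
  }
})

test_that("interval probabilities sum to one for every patient", {
  cohort <- make_simple_cohort(200, list(x1 = 0.6), seed = 8)
  fit <- fit_mtlr(cohort, lambda = 0.5)
  curves <- predict_survival_curve(fit, cohort[1:20, ])
  for (cv in curves) {
    # sum of interval masses = 1 - S(tau_m) + sum of drops = 1 exactly
    drops <- -diff(c(1, cv$probs[-1]))
    expect_equal(sum(drops) + cv$probs[length(cv$probs)], 1, tolerance = 1e-12)
  }
})

test_that("zero-parameter model predicts the uniform closed-form curve", {
  grid <- structure(list(tau = c(5, 10, 15, 20), m = 4L), class = "time_grid")
  curves <- isdkit:::mtlr_curves_encoded(matrix(0, 4, 1), rep(0, 4),
                                         grid, matrix(1))
  S <- curves[[1]]$probs[-1]
  expect_equal(S, (5 - 1:4) / 5, tolerance = 1e-12)
})

test_that("huge ridge penalty collapses to the covariate-free marginal model", {
  cohort <- make_simple_cohort(300, list(x1 = 1), seed = 15)
  fit <- fit_mtlr(cohort, lambda = 1e8)
  expect_lt(max(abs(fit$W)), 1e-3)
  cs <- predict_survival_curve(fit, cohort[c(1, 2, 3), ])
  expect_equal(cs[[1]]$probs, cs[[2]]$probs, tolerance = 1e-3)
  expect_equal(cs[[1]]$probs, cs[[3]]$probs, tolerance = 1e-3)
})

test_that("fitting is deterministic and recovers the null model on noise", {
  cohort <- make_simple_cohort(2000, list(x1 = 0, x2 = 0), seed = 23)
  f1 <- fit_mtlr(cohort, lambda = 1)
  f2 <- fit_mtlr(cohort, lambda = 1)
  expect_equal(f1$W, f2$W, tolerance = 1e-8)
  expect_equal(f1$b, f2$b, tolerance = 1e-8)
  # null covariates: weights centred on zero and predictions flat in x
  expect_lt(abs(mean(f1$W)), 0.02)
  expect_lt(mean(abs(f1$W)), 0.25)
  nd <- tibble::tibble(x1 = mean(cohort$x1) + c(-1, 1) * sd(cohort$x1),
                       x2 = mean(cohort$x2))
  cs <- predict_survival_curve(f1, nd)
  expect_lt(max(abs(cs[[1]]$probs - cs[[2]]$probs)), 0.06)
})

test_that("lambda selection behaves at the grid edges", {
  cohort <- make_simple_cohort(150, list(x1 = 0.5), seed = 31)
  d <- encode_design(cohort)
  expect_equal(select_lambda(d$X, cohort$time_months, cohort$event,
                             lambda_grid = 7), 7)
  l1 <- select_lambda(d$X, cohort$time_months, cohort$event,
                      lambda_grid = c(0.1, 10), k_inner = 3, seed = 5)
  l2 <- select_lambda(d$X, cohort$time_months, cohort$event,
                      lambda_grid = c(0.1, 10), k_inner = 3, seed = 5)
  expect_identical(l1, l2)
})

test_that("strong low-dimensional signal selects the light penalty", {
  cohort <- make_simple_cohort(1000, list(x1 = 1.2, x2 = -1.2), seed = 11,
                               binary = "x2")
  d <- encode_design(cohort)
  lam <- select_lambda(d$X, cohort$time_months, cohort$event,
                       lambda_grid = c(1e-4, 1e6), k_inner = 5, seed = 1)
  expect_equal(lam, 1e-4)
})

test_that("curves from a crossing-hazards model cross", {
  # effect reverses sign at 24 months: early harm, late benefit; the late
  # baseline hazard is high enough that the survival curves themselves cross
  cohort <- make_simple_cohort(
    2500, list(x = step_fn(c(1.2, -1.2), c(0, 24))), seed = 19,
    baseline = step_fn(c(0.012, 0.05), c(0, 24)),
    censoring = list(horizon = 120, uniform_prob = 0.3, uniform_max = 120),
    binary = "x"
  )
  fit <- fit_mtlr(cohort, lambda = 0.25)
  nd <- tibble::tibble(x = c(0, 1))
  cs <- predict_survival_curve(fit, nd)
  s0 <- cs[[1]]$probs[-1]; s1 <- cs[[2]]$probs[-1]
  expect_lt(s1[1], s0[1])                       # x=1 worse early
  m <- length(s0)
  expect_gt(s1[m], s0[m])                       # x=1 better late
})

test_that("mismatched covariates are rejected at prediction time", {
  cohort <- make_simple_cohort(100, list(x1 = 0.5), seed = 2)
  fit <- fit_mtlr(cohort, lambda = 1)
  expect_error(predict_survival_curve(fit, tibble::tibble(bad = 1)), "x1")
})

test_that("MTLR models survive a JSON round trip", {
  cohort <- make_simple_cohort(150, list(x1 = 0.7), seed = 4)
  fit <- fit_mtlr(cohort, lambda = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$W, fit$W, tolerance = 1e-12)
  expect_equal(back$b, fit$b, tolerance = 1e-12)
  expect_equal(back$grid$tau, fit$grid$tau, tolerance = 1e-12)
  c1 <- predict_survival_curve(fit, cohort[1, ])
  c2 <- predict_survival_curve(back, cohort[1, ])
  expect_equal(c1$probs, c2$probs, tolerance = 1e-12)
})
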