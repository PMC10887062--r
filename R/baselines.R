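#' Fit a Cox proportional hazards ISD model (Cox-KP)
#'
#' Cox partial likelihood (Breslow tie handling) via [survival::coxph()],
#' paired with the Kalbfleisch-Prentice self-consistent baseline survival
#' estimator so the model yields a full survival curve per patient.
#'
#' @param cohort A `cohort_table`.
#' @param standardize Standardize continuous covariates (default `TRUE`).
#' @return An object of class `cox_isd` with `beta`, `baseline` (tibble
#'   `time`, `surv`), the design metadata and the null/fitted log partial
#'   likelihoods.
#' @export
fit_cox <- function(cohort, standardize = TRUE) {
  if (sum(cohort$event) < 1) abort("need at least 1 event to fit a Cox model")
  design <- encode_design(cohort, standardize = standardize)
  X <- design$X
  times <- cohort$time_months; events <- cohort$event
  fit <- survival::coxph(survival::Surv(times, events) ~ X, ties = "breslow")
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 50)) {
    abort("Cox partial likelihood appears monotone (separation); consider fit_coxen()")
  }
  beta <- setNames(as.numeric(coef(fit)), design$columns)
  baseline <- kp_baseline(beta, X, times, events)
  design$X <- NULL
  structure(
    list(
      beta = beta, baseline = baseline, design = design, penalty = NULL,
      loglik = fit$loglik[2], null_loglik = fit$loglik[1],
      n = nrow(cohort), n_events = sum(events)
    ),
    class = "cox_isd"
  )
}

#' Kalbfleisch-Prentice baseline survival estimator
#'
#' At each distinct event time the survival factor alpha solves the KP
#' self-consistency equation
#' \deqn{\sum_{i \in D} \frac{e^{\eta_i}}{1 - \alpha^{e^{\eta_i}}} =
#'       \sum_{l \in R} e^{\eta_l},}
#' which for an untied event has the closed form
#' \eqn{\alpha = (1 - e^{\eta_i}/\sum_R e^{\eta_l})^{e^{-\eta_i}}}; tied
#' steps are solved numerically. The baseline is
#' \eqn{S_0(t) = \prod_{t_i \le t} \alpha_i}. With all coefficients zero it
#' reduces exactly to the Kaplan-Meier estimator.
#'
#' @param beta Fitted coefficients.
#' @param X Encoded design matrix (training data, same scale as `beta`).
#' @param times,events Training times and event indicators.
#' @return Tibble with `time` (distinct event times) and `surv` (S0).
#' @export
kp_baseline <- function(beta, X, times, events) {
  eta <- as.numeric(X %*% beta)
  r <- exp(eta)
  ev_times <- sort(unique(times[events == 1]))
  alpha <- vapply(ev_times, function(tt) {
    deaths <- which(events == 1 & times == tt)
    risk <- which(times >= tt)
    sr <- sum(r[risk])
    if (length(deaths) == 1) {
      ri <- r[deaths]
      base <- 1 - ri / sr
      if (base <= 0) return(0)
      return(base^(1 / ri))
    }
    rd <- r[deaths]
    # f is increasing in a on (0,1) with f -> +Inf as a -> 1
    f <- function(a) sum(rd / (1 - a^rd)) - sr
    lo <- 1e-12; hi <- 1 - 1e-12
    if (f(lo) >= 0) return(0)   # whole risk set dies: survival factor 0
    uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
  tibble::tibble(time = ev_times, surv = cumprod(alpha))
}

#' @export
print.cox_isd <- function(x, ...) {
  cat("<cox_isd> p = ", length(x$beta), " covariates, n = ", x$n,
      " (", x$n_events, " events)",
      if (!is.null(x$penalty)) paste0(", elastic net (alpha_en = ",
                                      format(x$penalty$alpha_en), ", l1_ratio = ",
                                      format(x$penalty$l1_ratio), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Predict a survival curve from a Cox-KP model
#'
#' \eqn{S(t|x) = S_0(t)^{\exp(\beta x)}} at the distinct training event
#' times, prepended with (0, 1). Curves from a single Cox model are ordered
#' by risk score and never cross.
#'
#' @param model A `cox_isd`.
#' @param newdata Data frame of raw covariates.
#' @return A [survival_curve()] or list thereof.
#' @export
predict_survival_curve.cox_isd <- function(model, newdata) {
  Xenc <- apply_design(model$design, newdata)
  lp <- as.numeric(Xenc %*% model$beta)
  curves <- lapply(lp, function(l) {
    survival_curve(c(0, model$baseline$time),
                   c(1, model$baseline$surv^exp(l)))
  })
  if (length(curves) == 1) curves[[1]] else curves
}

#' @export
predict.cox_isd <- function(object, newdata, ...) {
  predict_survival_curve.cox_isd(object, newdata)
}

#' @method tidy cox_isd
#' @export
tidy.cox_isd <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = as.numeric(x$beta))
}

#' @method glance cox_isd
#' @export
glance.cox_isd <- function(x, ...) {
  tibble::tibble(p = length(x$beta), n = x$n, n_events = x$n_events,
                 loglik = x$loglik %||% NA_real_)
}

#' Fit an elastic-net penalized Cox ISD model (CoxEN-KP)
#'
#' Minimizes the per-observation negative log partial likelihood plus
#' `alpha_en * (l1_ratio * |beta|_1 + (1 - l1_ratio)/2 * |beta|_2^2)`
#' (glmnet's objective scale) along a warm-started path ending at the
#' requested penalty, then attaches the Kalbfleisch-Prentice baseline at the
#' penalized coefficients. `alpha_en = NULL` selects the penalty by inner
#' cross-validation of the partial likelihood deviance.
#'
#' @param cohort A `cohort_table`.
#' @param alpha_en Penalty weight (>= 0), or `NULL` for inner-CV selection.
#' @param l1_ratio Elastic-net mixing in [0, 1]; default 0.5.
#' @param inner_k,seed Inner-CV folds and seed (used when `alpha_en = NULL`).
#' @param standardize Standardize continuous covariates (default `TRUE`).
#' @return A `cox_isd` with a `penalty` field.
#' @export
fit_coxen <- function(cohort, alpha_en = NULL, l1_ratio = 0.5,
                      inner_k = 5, seed = 1, standardize = TRUE) {
  if (sum(cohort$event) < 1) abort("need at least 1 event to fit")
  stopifnot(is.null(alpha_en) || alpha_en >= 0, l1_ratio >= 0, l1_ratio <= 1)
  design <- encode_design(cohort, standardize = standardize)
  X <- design$X
  y <- survival::Surv(cohort$time_months, cohort$event)
  if (is.null(alpha_en)) {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(inner_k), nrow(X)))
    cvfit <- glmnet::cv.glmnet(X, y, family = "cox", alpha = l1_ratio,
                               foldid = foldid, standardize = FALSE)
    alpha_en <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
  } else {
    lmax <- max(abs(t(X) %*% (cohort$event - mean(cohort$event)))) / nrow(X) * 2 + alpha_en
    path <- exp(seq(log(lmax + 1e-8), log(max(alpha_en, 1e-10)), length.out = 60))
    fit <- glmnet::glmnet(X, y, family = "cox", alpha = l1_ratio,
                          lambda = path, thresh = 1e-14, standardize = FALSE)
  }
  beta <- setNames(
    as.numeric(glmnet::coef.glmnet(fit, s = alpha_en, exact = FALSE)),
    design$columns
  )
  baseline <- kp_baseline(beta, X, cohort$time_months, cohort$event)
  design$X <- NULL
  structure(
    list(
      beta = beta, baseline = baseline, design = design,
      penalty = list(alpha_en = alpha_en, l1_ratio = l1_ratio),
      loglik = NULL, null_loglik = NULL,
      n = nrow(cohort), n_events = sum(cohort$event)
    ),
    class = "cox_isd"
  )
}

#' Fit a Weibull accelerated failure time ISD model
#'
#' Maximum likelihood for \eqn{\log T = \mu + \gamma x + \sigma W} with W
#' standard minimum extreme value, via [survival::survreg()]; the implied
#' ISD is \eqn{S(t|x) = \exp(-(t / e^{\mu + \gamma x})^{1/\sigma})}.
#'
#' @param cohort A `cohort_table`.
#' @param standardize Standardize continuous covariates (default `TRUE`).
#' @return An object of class `aft_isd` with `mu`, `gamma`, `sigma`.
#' @export
fit_weibull_aft <- function(cohort, standardize = TRUE) {
  if (sum(cohort$event) < 1) abort("need at least 1 event to fit")
  design <- encode_design(cohort, standardize = standardize)
  X <- design$X
  fit <- survival::survreg(
    survival::Surv(cohort$time_months, cohort$event) ~ X,
    dist = "weibull"
  )
  if (!is.null(fit$flag) && fit$flag != 0) abort("Weibull AFT fit did not converge")
  cf <- coef(fit)
  design$X <- NULL
  structure(
    list(
      mu = unname(cf[1]),
      gamma = setNames(as.numeric(cf[-1]), design$columns),
      sigma = fit$scale, design = design,
      loglik = fit$loglik[2],
      curve_times = sort(unique(cohort$time_months[cohort$event == 1])),
      n = nrow(cohort), n_events = sum(cohort$event)
    ),
    class = "aft_isd"
  )
}

#' @export
print.aft_isd <- function(x, ...) {
  cat("<aft_isd> Weibull AFT, p = ", length(x$gamma), ", sigma = ",
      format(x$sigma), ", n = ", x$n, " (", x$n_events, " events)\n", sep = "")
  invisible(x)
}

#' Predict a survival curve from a Weibull AFT model
#'
#' Evaluates the parametric survival function at the distinct training event
#' times (prepended with 0) so AFT curves share the representation of the
#' other ISD models.
#'
#' @param model An `aft_isd`.
#' @param newdata Data frame of raw covariates.
#' @return A [survival_curve()] or list thereof.
#' @export
predict_survival_curve.aft_isd <- function(model, newdata) {
  Xenc <- apply_design(model$design, newdata)
  lp <- model$mu + as.numeric(Xenc %*% model$gamma)
  tt <- model$curve_times
  curves <- lapply(lp, function(l) {
    survival_curve(c(0, tt), c(1, exp(-(tt / exp(l))^(1 / model$sigma))))
  })
  if (length(curves) == 1) curves[[1]] else curves
}

#' @export
predict.aft_isd <- function(object, newdata, ...) {
  predict_survival_curve.aft_isd(object, newdata)
}

#' @method tidy aft_isd
#' @export
tidy.aft_isd <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$gamma), "log(sigma)"),
    estimate = c(x$mu, as.numeric(x$gamma), log(x$sigma))
  )
}

#' @method glance aft_isd
#' @export
glance.aft_isd <- function(x, ...) {
  tibble::tibble(p = length(x$gamma), sigma = x$sigma, loglik = x$loglik,
                 n = x$n, n_events = x$n_events)
}

#' Adapter: wrap externally computed survival curves as an ISD model
#'
#' Lets any external model (e.g. a random survival forest) participate in
#' [cross_validated_evaluation()] by supplying a function mapping a
#' covariate data frame to a list of [survival_curve()]s.
#'
#' @param predict_fun `function(newdata) -> list of survival_curve`.
#' @param label Model label.
#' @return An `isd_adapter`.
#' @export
isd_adapter <- function(predict_fun, label = "external") {
  stopifnot(is.function(predict_fun))
  structure(list(predict_fun = predict_fun, label = label), class = "isd_adapter")
}

#' @export
predict_survival_curve.isd_adapter <- function(model, newdata) {
  curves <- model$predict_fun(newdata)
  if (inherits(curves, "survival_curve")) return(curves)
  if (length(curves) == 1) curves[[1]] else curves
}
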