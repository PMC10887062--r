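#' Step function specification for hazards and effects
#'
#' Piecewise-constant functions of time are described by `breaks` (segment
#' start times, first must be 0, strictly increasing) and `values` (one per
#' segment; the last segment extends to infinity).
#'
#' @param values Numeric vector of per-segment values.
#' @param breaks Numeric vector of segment start times, first = 0.
#' @return A `step_fn` list.
#' @export
step_fn <- function(values, breaks = 0) {
  breaks <- as.numeric(breaks); values <- as.numeric(values)
  if (length(breaks) != length(values)) abort("breaks and values must have equal length")
  if (breaks[1] != 0) abort("first break must be 0")
  if (is.unsorted(breaks, strictly = TRUE)) abort("breaks must be strictly increasing")
  structure(list(breaks = breaks, values = values), class = "step_fn")
}

step_value <- function(f, t) f$values[pmax(1L, findInterval(t, f$breaks))]

#' Configuration for the synthetic gastric-cancer cohort generator
#'
#' Defaults emulate the covariate marginals of a pooled gastric
#' adenocarcinoma cohort (advanced-stage mix, 66\% male, 71\% adjuvant
#' chemotherapy, age median 59 with IQR roughly 49-67) together with a
#' piecewise-constant baseline hazard and time-varying log-hazard effects:
#' chemotherapy protective early then null after 24 months, Stage IV
#' constantly harmful, Stage III harmful only after 12 months, and a
#' tumour-microenvironment (TME) score whose protective effect is strongest
#' late. Molecular subtype scores are Dirichlet-distributed classifier
#' probabilities (one simplex per classifier).
#'
#' Effects are keyed by encoded covariate name (`"treatment=Yes"`,
#' `"stage=IV"`, continuous score names, `"age"`); the age effect applies to
#' age centred at `age$location` so the baseline hazard describes a
#' cohort-typical patient.
#'
#' @param n Cohort size.
#' @param stage_probs,sex_probs,lauren_probs,location_probs,treatment_probs
#'   Named category probabilities (must sum to 1).
#' @param age List: `location`, `scale`, `lower`, `upper` of a truncated
#'   normal in years.
#' @param tcga_alpha,acrg_alpha Dirichlet concentration vectors for the two
#'   molecular subtype classifiers.
#' @param tme_beta Length-2 Beta shape parameters for the TME-high score.
#' @param baseline [step_fn()] of baseline hazard rates per month (all > 0).
#' @param effects Named list of [step_fn()] log-hazard-ratio profiles (or
#'   single numbers, treated as time-constant).
#' @param censoring List: `horizon` (administrative censoring, months),
#'   `uniform_prob` (probability a patient also has a uniform dropout time),
#'   `uniform_max` (upper limit of that uniform).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    n = 1043,
    stage_probs = c(I = 170, II = 330, III = 339, IV = 204) / 1043,
    sex_probs = c(Female = 359, Male = 684) / 1043,
    lauren_probs = c(Intestinal = 504, Diffuse = 495, Mixed = 44) / 1043,
    location_probs = c(Distal = 537, Proximal = 482, Whole = 24) / 1043,
    treatment_probs = c(No = 299, Yes = 744) / 1043,
    age = list(location = 59, scale = 13.3, lower = 20, upper = 90),
    tcga_alpha = 4 * c(CIN = 824, EBV = 43, GS = 66, MSI = 110) / 1043,
    acrg_alpha = 4 * c(EMT = 118, MSI = 162, MSSTP53neg = 412, MSSTP53pos = 351) / 1043,
    tme_beta = c(1.83, 2.17),
    baseline = step_fn(c(0.018, 0.013, 0.0075, 0.0045), c(0, 12, 36, 72)),
    effects = list(
      "treatment=Yes" = step_fn(c(-0.7, 0), c(0, 24)),
      "stage=II" = 0.25,
      "stage=III" = step_fn(c(0, 0.6), c(0, 12)),
      "stage=IV" = 0.9,
      "sex=Male" = 0.1,
      "age" = 0.015,
      "acrg_EMT" = 0.5,
      "tme_high" = step_fn(c(-0.2, -0.8), c(0, 60))
    ),
    censoring = list(horizon = 120, uniform_prob = 1, uniform_max = 120)) {
  for (p in list(stage_probs, sex_probs, lauren_probs, location_probs, treatment_probs)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) abort("category probabilities must be in [0,1] and sum to 1")
  }
  if (any(baseline$values <= 0)) abort("baseline hazard rates must be strictly positive")
  effects <- lapply(effects, function(e) if (inherits(e, "step_fn")) e else step_fn(e))
  stopifnot(censoring$horizon > 0, censoring$uniform_prob >= 0, censoring$uniform_prob <= 1)
  structure(
    list(
      n = n, stage_probs = stage_probs, sex_probs = sex_probs,
      lauren_probs = lauren_probs, location_probs = location_probs,
      treatment_probs = treatment_probs, age = age,
      tcga_alpha = tcga_alpha, acrg_alpha = acrg_alpha, tme_beta = tme_beta,
      baseline = baseline, effects = effects, censoring = censoring
    ),
    class = "synthetic_config"
  )
}

#' Default covariate schema for the synthetic gastric cohort
#'
#' Continuous classifier scores enter per class with one reference class per
#' classifier held out (the simplex constraint makes the full set collinear):
#' genomically-stable for the TCGA classifier, MSS TP53-positive for the ACRG
#' classifier. Reference levels for the categorical covariates are Stage I,
#' Female, Lauren Intestinal, Distal location and no chemotherapy.
#'
#' @return A [cohort_schema()].
#' @export
gastric_schema <- function() {
  cohort_schema(
    continuous = c("age", "tcga_CIN", "tcga_EBV", "tcga_MSI",
                   "acrg_EMT", "acrg_MSI", "acrg_MSSTP53neg", "tme_high"),
    categorical = list(
      stage = c("I", "II", "III", "IV"),
      sex = c("Female", "Male"),
      lauren = c("Intestinal", "Diffuse", "Mixed"),
      location = c("Distal", "Proximal", "Whole"),
      treatment = c("No", "Yes")
    )
  )
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n, length(alpha), byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

rtruncnorm1 <- function(n, location, scale, lower, upper) {
  plo <- stats::pnorm(lower, location, scale)
  phi <- stats::pnorm(upper, location, scale)
  stats::qnorm(runif(n, plo, phi), location, scale)
}

# merged segment grid + per-patient rate matrix for h(t|x) = h0(t) exp(sum beta_c(t) x_c)
hazard_segments <- function(config, X) {
  breaks <- sort(unique(c(config$baseline$breaks,
                          unlist(lapply(config$effects, `[[`, "breaks")))))
  h0 <- step_value(config$baseline, breaks)
  eta <- matrix(0, nrow(X), length(breaks))
  for (nm in names(config$effects)) {
    if (!nm %in% colnames(X)) abort(paste0("effect covariate '", nm, "' not in design"))
    eta <- eta + outer(X[, nm], step_value(config$effects[[nm]], breaks))
  }
  rates <- sweep(exp(eta), 2, h0, `*`)
  if (any(rates <= 0)) abort("degenerate hazard: non-positive rate segment")
  list(breaks = breaks, rates = rates)
}

#' Sample event times from a piecewise-exponential hazard
#'
#' Inverts the cumulative hazard \eqn{H(t|x)} segment by segment in closed
#' form against an exponential deviate, for the model
#' \eqn{h(t|x) = h_0(t)\exp(\sum_c \beta_c(t) x_c)} with piecewise-constant
#' \eqn{h_0} and \eqn{\beta_c}.
#'
#' @param X Numeric matrix of raw-encoded covariates with columns matching
#'   effect names (dummies and scores; age already centred).
#' @param config A [synthetic_config()] (its `baseline` and `effects` are used).
#' @return Numeric vector of event times (months), one per row of `X`.
#' @export
sample_event_time <- function(X, config) {
  seg <- hazard_segments(config, X)
  n <- nrow(X); S <- length(seg$breaks)
  target <- rexp(n)
  t_out <- rep(NA_real_, n); cum <- numeric(n)
  for (s in seq_len(S)) {
    width <- if (s < S) seg$breaks[s + 1] - seg$breaks[s] else Inf
    add <- seg$rates[, s] * width
    hit <- is.na(t_out) & (target <= cum + add)
    t_out[hit] <- seg$breaks[s] + (target[hit] - cum[hit]) / seg$rates[hit, s]
    cum <- cum + add
  }
  t_out
}

#' True survival probability under the generating hazard
#'
#' Closed-form \eqn{S(t|x) = \exp(-H(t|x))} of the piecewise-exponential
#' generator; used as a known-truth oracle for calibration studies.
#'
#' @inheritParams sample_event_time
#' @param t Query times: a scalar, or one time per row of `X`.
#' @return Vector of survival probabilities.
#' @export
true_survival_prob <- function(X, config, t) {
  if (nrow(X) == 1 && length(t) > 1) X <- X[rep(1, length(t)), , drop = FALSE]
  seg <- hazard_segments(config, X)
  t <- rep_len(t, nrow(X))
  S <- length(seg$breaks)
  H <- numeric(nrow(X))
  for (s in seq_len(S)) {
    upper <- if (s < S) seg$breaks[s + 1] else Inf
    overlap <- pmax(0, pmin(t, upper) - seg$breaks[s])
    H <- H + seg$rates[, s] * overlap
  }
  exp(-H)
}

#' Apply administrative plus uniform censoring
#'
#' Each patient's censoring time is the administrative horizon; with
#' probability `uniform_prob` it is the minimum of the horizon and an
#' independent Uniform(0, `uniform_max`) dropout time. Observed time is
#' min(T, C), event = (T <= C).
#'
#' @param true_times Vector of uncensored event times.
#' @param censoring_spec List with `horizon`, `uniform_prob`, `uniform_max`.
#' @return A tibble with `observed`, `event`, `censor_time`; attribute
#'   `censoring_fraction` holds the achieved fraction.
#' @export
apply_censoring <- function(true_times, censoring_spec) {
  n <- length(true_times)
  C <- rep(censoring_spec$horizon, n)
  has_u <- runif(n) < censoring_spec$uniform_prob
  C[has_u] <- pmin(C[has_u], runif(sum(has_u), 0, censoring_spec$uniform_max))
  observed <- pmin(true_times, C)
  event <- as.integer(true_times <= C)
  out <- tibble::tibble(observed = observed, event = event, censor_time = C)
  attr(out, "censoring_fraction") <- mean(event == 0)
  out
}

# raw-encoded design (dummies/scores, age centred) from drawn covariates
raw_encode <- function(df, config) {
  X <- cbind(
    age = df$age - config$age$location,
    "stage=II" = as.numeric(df$stage == "II"),
    "stage=III" = as.numeric(df$stage == "III"),
    "stage=IV" = as.numeric(df$stage == "IV"),
    "sex=Male" = as.numeric(df$sex == "Male"),
    "lauren=Diffuse" = as.numeric(df$lauren == "Diffuse"),
    "lauren=Mixed" = as.numeric(df$lauren == "Mixed"),
    "location=Proximal" = as.numeric(df$location == "Proximal"),
    "location=Whole" = as.numeric(df$location == "Whole"),
    "treatment=Yes" = as.numeric(df$treatment == "Yes"),
    tcga_CIN = df$tcga_CIN, tcga_EBV = df$tcga_EBV,
    tcga_GS = df$tcga_GS, tcga_MSI = df$tcga_MSI,
    acrg_EMT = df$acrg_EMT, acrg_MSI = df$acrg_MSI,
    acrg_MSSTP53neg = df$acrg_MSSTP53neg, acrg_MSSTP53pos = df$acrg_MSSTP53pos,
    tme_high = df$tme_high
  )
  X
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates independently from the configured marginals, event times
#' from the piecewise-exponential hazard, and applies censoring. Fully
#' reproducible under `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with `cohort` (a `cohort_table` under [gastric_schema()]) and
#'   `truth` (tibble of true/censor times with the raw-encoded design and the
#'   config in attributes).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$n
  draw_cat <- function(p) factor(
    sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  df <- tibble::tibble(
    id = sprintf("SIM%05d", seq_len(n)),
    age = rtruncnorm1(n, config$age$location, config$age$scale,
                      config$age$lower, config$age$upper),
    stage = draw_cat(config$stage_probs),
    sex = draw_cat(config$sex_probs),
    lauren = draw_cat(config$lauren_probs),
    location = draw_cat(config$location_probs),
    treatment = draw_cat(config$treatment_probs)
  )
  tcga <- rdirichlet(n, config$tcga_alpha)
  colnames(tcga) <- paste0("tcga_", names(config$tcga_alpha))
  acrg <- rdirichlet(n, config$acrg_alpha)
  colnames(acrg) <- paste0("acrg_", names(config$acrg_alpha))
  df <- dplyr::bind_cols(df, tibble::as_tibble(tcga), tibble::as_tibble(acrg))
  df$tme_high <- stats::rbeta(n, config$tme_beta[1], config$tme_beta[2])

  X <- raw_encode(df, config)
  true_time <- sample_event_time(X, config)
  cens <- apply_censoring(true_time, config$censoring)

  df$time_months <- cens$observed
  df$event <- cens$event
  cohort <- as_cohort(df, gastric_schema())
  truth <- tibble::tibble(
    id = df$id, true_time = true_time,
    censor_time = cens$censor_time,
    observed = cens$observed, event = cens$event
  )
  attr(truth, "design") <- X
  attr(truth, "config") <- config
  attr(truth, "censoring_fraction") <- attr(cens, "censoring_fraction")
  list(cohort = cohort, truth = truth)
}
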