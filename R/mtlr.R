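#' Build the MTLR time grid from training data
#'
#' The number of discretization points scales with the number of uncensored
#' patients, m = ceiling(sqrt(n_uncensored)), and the points are placed at
#' the j/(m+1) empirical quantiles (type 7) of the uncensored event times,
#' de-duplicated (ties can shrink m).
#'
#' @param times Observed times (months).
#' @param events Event indicators (1 = death observed).
#' @return A `time_grid` object with fields `tau` and `m`.
#' @export
build_time_grid <- function(times, events) {
  ev_times <- times[events == 1]
  if (length(ev_times) == 0) abort("no uncensored records: cannot build a time grid")
  m <- ceiling(sqrt(length(ev_times)))
  tau <- unname(quantile(ev_times, probs = seq_len(m) / (m + 1), type = 7))
  tau <- unique(tau)
  structure(list(tau = tau, m = length(tau)), class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat("<time_grid> m = ", x$m, ", tau in [", format(min(x$tau)), ", ",
      format(max(x$tau)), "]\n", sep = "")
  invisible(x)
}

# interval index k(t): smallest k with t <= tau_k, else m+1 (intervals (tau_{k-1}, tau_k])
interval_index <- function(t, tau) {
  vapply(t, function(ti) sum(tau < ti) + 1L, integer(1))
}

# per-patient outcome mask over the m+1 death intervals:
# uncensored -> one-hot at the containing interval; censored at c ->
# all intervals not contradicted by survival to c: {k : tau_k >= c} + {m+1}
mtlr_outcome_mask <- function(times, events, grid, censored_inclusive = TRUE) {
  m <- grid$m; n <- length(times)
  mask <- matrix(FALSE, n, m + 1)
  for (i in seq_len(n)) {
    if (events[i] == 1) {
      mask[i, interval_index(times[i], grid$tau)] <- TRUE
    } else {
      a <- interval_index(times[i], grid$tau)
      if (!censored_inclusive) a <- a + 1L
      a <- min(a, m + 1L)
      mask[i, a:(m + 1)] <- TRUE
    }
  }
  mask
}

row_logsumexp <- function(M) {
  rmax <- as.numeric(do.call(pmax, asplit(M, 2)))
  rmax + log(rowSums(exp(M - rmax)))
}

# value + gradient of the regularized negative log-likelihood at packed
# parameters par = c(vec(W), b), W an m x p matrix (rows = time points)
mtlr_value_grad <- function(par, X, mask, grid, lambda, smooth_lambda = 0,
                            A = NULL, B = NULL) {
  m <- grid$m; p <- ncol(X); n <- nrow(X)
  W <- matrix(par[seq_len(m * p)], m, p)
  b <- par[m * p + seq_len(m)]
  if (is.null(A)) A <- outer(seq_len(m), seq_len(m), `>=`) * 1  # A[j,k] = 1(j >= k)
  Theta <- X %*% t(W) + matrix(b, n, m, byrow = TRUE) # n x m
  logU <- cbind(Theta %*% A, 0)                       # n x (m+1); logU[, m+1] = 0
  logZ <- row_logsumexp(logU)
  logUm <- logU
  logUm[!mask] <- -Inf
  logN <- row_logsumexp(logUm)
  value <- sum(logZ - logN) + lambda / 2 * sum(W^2)

  P <- exp(logU - logZ)
  Q <- exp(logUm - logN)
  Q[!mask] <- 0
  if (is.null(B)) B <- outer(seq_len(m + 1), seq_len(m), `<=`) * 1  # B[k,j] = 1(k <= j)
  G <- (P - Q) %*% B                                  # n x m, d/d theta_j
  gradW <- t(G) %*% X + lambda * W
  gradb <- colSums(G)
  if (smooth_lambda > 0 && m > 1) {
    Dw <- diff(W)
    value <- value + smooth_lambda / 2 * sum(Dw^2)
    L <- matrix(0, m, p)
    L[-m, ] <- L[-m, , drop = FALSE] - Dw
    L[-1, ] <- L[-1, , drop = FALSE] + Dw
    gradW <- gradW + smooth_lambda * L
  }
  list(value = value, grad = c(as.numeric(gradW), gradb))
}

#' MTLR objective value and gradient
#'
#' The regularized censored negative log-likelihood of the multi-task
#' logistic regression survival model. With time points
#' \eqn{\tau_1 < \dots < \tau_m} and per-time scores
#' \eqn{\theta_j(x) = w_j \cdot x + b_j}, the unnormalized score of death in
#' interval k (half-open \eqn{(\tau_{k-1}, \tau_k]}, with interval m+1
#' beyond the grid) is \eqn{u_k(x) = \exp(\sum_{j \ge k} \theta_j(x))},
#' \eqn{u_{m+1} = 1}. Uncensored patients contribute
#' \eqn{-\log(u_{k(t)}/Z)}; censored patients the log of the normalized mass
#' of all intervals not contradicted by survival to the censoring time. A
#' ridge penalty \eqn{(\lambda/2)\|W\|_F^2} acts on the weights only (biases
#' unpenalized). Log-sum-exp stabilization guards against overflow.
#'
#' @param W m x p weight matrix.
#' @param b Length-m bias vector.
#' @param X n x p encoded design matrix.
#' @param times,events Observed times and event indicators.
#' @param grid A [build_time_grid()] result.
#' @param lambda Ridge penalty weight (>= 0).
#' @param smooth_lambda Optional adjacent-time smoothness penalty
#'   \eqn{(\mu/2)\sum_j \|w_{j+1}-w_j\|^2}; default 0 (off).
#' @param censored_inclusive Include the interval containing the censoring
#'   time in a censored patient's outcome set (default `TRUE`).
#' @return List with `value` (scalar) and `grad_W`, `grad_b`.
#' @export
mtlr_objective <- function(W, b, X, times, events, grid, lambda = 0,
                           smooth_lambda = 0, censored_inclusive = TRUE) {
  mask <- mtlr_outcome_mask(times, events, grid, censored_inclusive)
  vg <- mtlr_value_grad(c(as.numeric(W), b), X, mask, grid, lambda, smooth_lambda)
  m <- grid$m; p <- ncol(X)
  list(
    value = vg$value,
    grad_W = matrix(vg$grad[seq_len(m * p)], m, p),
    grad_b = vg$grad[m * p + seq_len(m)]
  )
}

fit_mtlr_design <- function(X, times, events, grid, lambda,
                            smooth_lambda = 0, censored_inclusive = TRUE,
                            tol = 1e-6, factr = 100, max_restarts = 5L) {
  m <- grid$m; p <- ncol(X)
  mask <- mtlr_outcome_mask(times, events, grid, censored_inclusive)
  A <- outer(seq_len(m), seq_len(m), `>=`) * 1
  B <- outer(seq_len(m + 1), seq_len(m), `<=`) * 1
  # optim calls fn and gr at the same point back to back: cache one evaluation
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$vg)
    vg <- mtlr_value_grad(par, X, mask, grid, lambda, smooth_lambda, A, B)
    cache$par <- par; cache$vg <- vg
    vg
  }
  fn <- function(par) eval_at(par)$value
  gr <- function(par) eval_at(par)$grad
  par <- numeric(m * p + m)
  val <- NA_real_; gnorm <- Inf
  for (r in seq_len(max_restarts)) {
    opt <- if (r %% 2 == 1) {
      optim(par, fn, gr, method = "L-BFGS-B",
            control = list(maxit = 2000L, factr = factr))
    } else {
      # full-memory BFGS polish when limited-memory stalls short of the tol
      optim(par, fn, gr, method = "BFGS",
            control = list(maxit = 5000L, reltol = 1e-16))
    }
    par <- opt$par
    val <- opt$value
    gnorm <- sqrt(sum(gr(par)^2))
    if (gnorm <= tol * max(1, abs(val))) break
  }
  if (gnorm > tol * max(1, abs(val))) {
    abort(paste0("MTLR optimizer did not converge: gradient norm ",
                 format(gnorm), " at objective ", format(val)))
  }
  W <- matrix(par[seq_len(m * p)], m, p,
              dimnames = list(NULL, colnames(X)))
  b <- par[m * p + seq_len(m)]
  nll <- mtlr_value_grad(par, X, mask, grid, 0, 0)$value
  list(W = W, b = b, value = val, loglik = -nll, grad_norm = gnorm)
}

# mean out-of-fold log-likelihood per patient for one lambda (inner CV)
inner_cv_loglik <- function(X, times, events, lambda, k_inner, seed,
                            smooth_lambda = 0) {
  folds <- stratified_kfold_split(tibble::tibble(event = events), k = k_inner, seed = seed)
  ll <- vapply(folds, function(fd) {
    tr <- fd$train; te <- fd$test
    if (sum(events[tr]) == 0 || length(te) == 0) return(NA_real_)
    g <- build_time_grid(times[tr], events[tr])
    fit <- fit_mtlr_design(X[tr, , drop = FALSE], times[tr], events[tr], g,
                           lambda, smooth_lambda, tol = 1e-3, factr = 1e7,
                           max_restarts = 2L)
    mask_te <- mtlr_outcome_mask(times[te], events[te], g)
    vg <- mtlr_value_grad(c(as.numeric(fit$W), fit$b),
                          X[te, , drop = FALSE], mask_te, g, 0, 0)
    -vg$value / length(te)
  }, numeric(1))
  mean(ll, na.rm = TRUE)
}

#' Select the MTLR ridge penalty by inner cross-validation
#'
#' Maximizes the mean out-of-fold log-likelihood over a penalty grid using
#' stratified inner k-fold CV on the training data only; ties break toward
#' the larger (more regularized) value.
#'
#' @param X Encoded design matrix.
#' @param times,events Observed times and event indicators.
#' @param lambda_grid Candidate penalties; default powers of 4 from 2^-6 to 2^6.
#' @param k_inner Inner folds (default 5).
#' @param seed Integer seed for the inner split.
#' @return The selected lambda.
#' @export
select_lambda <- function(X, times, events, lambda_grid = 4^(-3:3),
                          k_inner = 5, seed = 1) {
  if (!length(lambda_grid)) abort("lambda_grid must be non-empty")
  if (length(lambda_grid) == 1) return(lambda_grid)
  lambda_grid <- sort(lambda_grid)
  ll <- vapply(lambda_grid, function(lam)
    inner_cv_loglik(X, times, events, lam, k_inner, seed), numeric(1))
  lambda_grid[max(which(ll >= max(ll) - 1e-12))]
}

#' Fit a multi-task logistic regression survival model
#'
#' Discretizes time from the training data ([build_time_grid()]), encodes
#' covariates ([encode_design()]), and minimizes the convex regularized
#' censored negative log-likelihood ([mtlr_objective()]) by quasi-Newton
#' (L-BFGS) from a zero start, giving a deterministic optimum.
#'
#' @param cohort A `cohort_table`.
#' @param lambda Ridge penalty; if `NULL`, chosen by inner CV over
#'   `lambda_grid` via [select_lambda()].
#' @param lambda_grid,inner_k,seed Inner-CV settings (used when
#'   `lambda = NULL`).
#' @param standardize Standardize continuous covariates (default `TRUE`).
#' @param smooth_lambda Optional adjacent-time smoothness penalty (default 0).
#' @param censored_inclusive See [mtlr_objective()].
#' @return An object of class `mtlr_fit`.
#' @export
fit_mtlr <- function(cohort, lambda = NULL, lambda_grid = 4^(-3:3),
                     inner_k = 5, seed = 1, standardize = TRUE,
                     smooth_lambda = 0, censored_inclusive = TRUE) {
  if (sum(cohort$event) < 2) abort("need at least 2 uncensored records to fit")
  design <- encode_design(cohort, standardize = standardize)
  times <- cohort$time_months; events <- cohort$event
  grid <- build_time_grid(times, events)
  if (is.null(lambda)) {
    lambda <- select_lambda(design$X, times, events, lambda_grid, inner_k, seed)
  }
  fit <- fit_mtlr_design(design$X, times, events, grid, lambda,
                         smooth_lambda, censored_inclusive)
  design$X <- NULL
  structure(
    list(
      W = fit$W, b = fit$b, grid = grid, lambda = lambda,
      smooth_lambda = smooth_lambda, design = design,
      loglik = fit$loglik, grad_norm = fit$grad_norm,
      n = nrow(cohort), n_events = sum(events)
    ),
    class = "mtlr_fit"
  )
}

#' @export
print.mtlr_fit <- function(x, ...) {
  cat("<mtlr_fit> m = ", x$grid$m, " time points, p = ", ncol(x$W),
      " covariates, lambda = ", format(x$lambda), ", n = ", x$n,
      " (", x$n_events, " events)\n", sep = "")
  invisible(x)
}

# survival curve from packed parameters for encoded rows (matrix)
mtlr_curves_encoded <- function(W, b, grid, Xenc) {
  m <- grid$m; n <- nrow(Xenc)
  A <- outer(seq_len(m), seq_len(m), `>=`) * 1
  Theta <- Xenc %*% t(W) + matrix(b, n, m, byrow = TRUE)
  logU <- cbind(Theta %*% A, 0)
  logZ <- row_logsumexp(logU)
  P <- exp(logU - logZ)
  Srev <- t(apply(P[, (m + 1):1, drop = FALSE], 1, cumsum))
  S <- Srev[, (m + 1):1, drop = FALSE][, -1, drop = FALSE] # S(tau_j) = sum_{k>j} P_k
  lapply(seq_len(n), function(i) {
    survival_curve(c(0, grid$tau), c(1, pmax(0, pmin(1, S[i, ]))))
  })
}

#' Predict individual survival distributions from an MTLR fit
#'
#' \eqn{S(\tau_j | x) = \sum_{k>j} u_k(x) / Z(x)}, prepended with (0, 1).
#' Because MTLR places no proportional-hazards constraint on the per-time
#' weights, predicted curves for different patients can cross.
#'
#' @param model An `mtlr_fit`.
#' @param newdata A data frame of raw covariates matching the model schema.
#' @return A list of [survival_curve()] objects (length `nrow(newdata)`),
#'   or a single curve when `newdata` has one row.
#' @export
predict_survival_curve <- function(model, newdata) {
  UseMethod("predict_survival_curve")
}

#' @export
predict_survival_curve.mtlr_fit <- function(model, newdata) {
  Xenc <- apply_design(model$design, newdata)
  if (ncol(Xenc) != ncol(model$W)) abort("covariate length does not match the fit")
  curves <- mtlr_curves_encoded(model$W, model$b, model$grid, Xenc)
  if (length(curves) == 1) curves[[1]] else curves
}

#' @export
predict.mtlr_fit <- function(object, newdata, ...) {
  predict_survival_curve.mtlr_fit(object, newdata)
}

#' @method tidy mtlr_fit
#' @export
tidy.mtlr_fit <- function(x, ...) {
  W <- x$W
  tibble::tibble(
    term = rep(colnames(W), each = nrow(W)),
    tau = rep(x$grid$tau, ncol(W)),
    weight = as.numeric(W)
  )
}

#' @method glance mtlr_fit
#' @export
glance.mtlr_fit <- function(x, ...) {
  tibble::tibble(
    m = x$grid$m, p = ncol(x$W), lambda = x$lambda,
    loglik = x$loglik, grad_norm = x$grad_norm,
    n = x$n, n_events = x$n_events
  )
}

#' Serialize a fitted ISD model to JSON
#'
#' Writes a self-describing JSON file (model type, time grid, parameters,
#' encoded column names, scaling constants and schema) that
#' [read_model_json()] restores for later prediction.
#'
#' @param model An `mtlr_fit`, `cox_isd` or `aft_isd`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  schema <- model$design$schema
  payload <- list(
    type = class(model)[1],
    columns = model$design$columns,
    center = as.list(model$design$center),
    scale = as.list(model$design$scale),
    standardize = model$design$standardize,
    schema = list(continuous = schema$continuous, categorical = schema$categorical),
    n = model$n, n_events = model$n_events
  )
  if (inherits(model, "mtlr_fit")) {
    payload$tau <- model$grid$tau
    payload$W <- apply(model$W, 1, identity, simplify = FALSE)
    payload$b <- model$b
    payload$lambda <- model$lambda
  } else if (inherits(model, "cox_isd")) {
    payload$beta <- as.list(model$beta)
    payload$baseline_times <- model$baseline$time
    payload$baseline_surv <- model$baseline$surv
    payload$penalty <- model$penalty
  } else if (inherits(model, "aft_isd")) {
    payload$mu <- model$mu; payload$gamma <- as.list(model$gamma)
    payload$sigma <- model$sigma
    payload$curve_times <- model$curve_times
  } else {
    abort("unsupported model class for serialization")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- cohort_schema(
    continuous = as.character(pl$schema$continuous %||% character()),
    categorical = lapply(pl$schema$categorical, as.character)
  )
  design <- structure(
    list(
      X = NULL, columns = pl$columns,
      center = unlist(pl$center)[pl$columns],
      scale = unlist(pl$scale)[pl$columns],
      zero_variance = character(), schema = schema,
      standardize = isTRUE(pl$standardize)
    ),
    class = "covariate_design"
  )
  base <- list(design = design, n = pl$n, n_events = pl$n_events)
  if (pl$type == "mtlr_fit") {
    W <- pl$W
    if (is.list(W)) W <- do.call(rbind, lapply(W, unlist))
    if (is.null(dim(W))) W <- matrix(W, ncol = length(pl$columns))
    colnames(W) <- pl$columns
    return(structure(
      c(base, list(W = W, b = pl$b, lambda = pl$lambda,
                   grid = structure(list(tau = pl$tau, m = length(pl$tau)),
                                    class = "time_grid"))),
      class = "mtlr_fit"
    ))
  }
  if (pl$type == "cox_isd") {
    return(structure(
      c(base, list(beta = setNames(unlist(pl$beta), pl$columns),
                   baseline = tibble::tibble(time = pl$baseline_times,
                                             surv = pl$baseline_surv),
                   penalty = pl$penalty)),
      class = "cox_isd"
    ))
  }
  if (pl$type == "aft_isd") {
    return(structure(
      c(base, list(mu = pl$mu, gamma = setNames(unlist(pl$gamma), pl$columns),
                   sigma = pl$sigma, curve_times = pl$curve_times)),
      class = "aft_isd"
    ))
  }
  abort(paste0("unknown model type in JSON: ", pl$type))
}
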