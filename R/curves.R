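#' Construct an individual survival curve
#'
#' A survival curve is a set of knots `(times, probs)` with `times[1] = 0`,
#' `probs[1] = 1`, probabilities in [0, 1] and non-increasing. Monotonicity
#' violations larger than 1e-9 are errors; smaller floating-point wiggles are
#' clamped.
#'
#' @param times Increasing knot times starting at 0 (months).
#' @param probs Survival probabilities at the knots.
#' @return A `survival_curve` object.
#' @export
survival_curve <- function(times, probs) {
  times <- as.numeric(times); probs <- as.numeric(probs)
  if (length(times) != length(probs) || length(times) < 2) {
    abort("a survival curve needs at least 2 (time, prob) knots")
  }
  if (times[1] != 0) abort("curve must start at time 0")
  if (is.unsorted(times, strictly = TRUE)) abort("knot times must be strictly increasing")
  if (abs(probs[1] - 1) > 1e-9) abort("curve must start at probability 1")
  if (any(probs < -1e-9 | probs > 1 + 1e-9)) abort("probabilities must lie in [0,1]")
  if (any(diff(probs) > 1e-9)) abort("survival probabilities must be non-increasing")
  probs[1] <- 1
  probs <- pmin(1, pmax(0, cummin(probs)))
  structure(list(times = times, probs = probs), class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve> ", length(x$times), " knots over [0, ",
      format(max(x$times)), "] months\n", sep = "")
  invisible(x)
}

#' Monotone cubic interpolator of a survival curve
#'
#' Builds a C1 monotone-preserving cubic Hermite interpolant through the
#' knots (Hyman-filtered slopes, the convention used for ISD survival-curve
#' queries); evaluations between knots never overshoot the neighbouring knot
#' values, and flat segments stay flat.
#'
#' @param curve A [survival_curve()].
#' @return A function of time, valid on `[0, max(times)]`.
#' @export
monotone_spline <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  splinefun(curve$times, curve$probs, method = "hyman")
}

last_slope <- function(curve) {
  k <- length(curve$times)
  (curve$probs[k] - curve$probs[k - 1]) / (curve$times[k] - curve$times[k - 1])
}

#' Survival probability at arbitrary times
#'
#' Spline evaluation inside the knot range; beyond the last knot the curve is
#' continued linearly with the final knot-segment slope and floored at 0.
#'
#' @param curve A [survival_curve()].
#' @param t Non-negative query times (vectorized).
#' @return Survival probabilities at `t`.
#' @export
survival_at_time <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(t < 0)) abort("query time must be non-negative")
  f <- monotone_spline(curve)
  t_max <- max(curve$times)
  out <- numeric(length(t))
  inside <- t <= t_max
  if (any(inside)) out[inside] <- pmin(1, pmax(0, f(t[inside])))
  if (any(!inside)) {
    p_last <- curve$probs[length(curve$probs)]
    out[!inside] <- pmax(0, p_last + last_slope(curve) * (t[!inside] - t_max))
  }
  out
}

#' Median survival time of a curve
#'
#' The time at which the monotone interpolant (with the same linear
#' extension as [survival_at_time()]) crosses survival probability 0.5,
#' root-bracketed to 1e-6 months. Returns `NA` ("not reached") when the
#' extended curve never reaches 0.5.
#'
#' @param curve A [survival_curve()].
#' @return Median survival in months, or `NA_real_` if not reached.
#' @export
median_survival_time <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  p <- curve$probs; tt <- curve$times
  k <- length(p)
  hit <- which(p <= 0.5)
  if (length(hit)) {
    i <- hit[1]
    if (p[i] == 0.5) return(tt[i])
    f <- monotone_spline(curve)
    return(uniroot(function(x) f(x) - 0.5, lower = tt[i - 1], upper = tt[i],
                   tol = 1e-6)$root)
  }
  sl <- last_slope(curve)
  if (sl >= 0) return(NA_real_)
  tt[k] + (p[k] - 0.5) / (-sl)
}

#' Restricted mean survival time
#'
#' Area under the monotone interpolant (with linear extension floored at 0)
#' from 0 to `t_max` — the integral summary of the curve, complementary to
#' the median crossing time.
#'
#' @param curve A [survival_curve()].
#' @param t_max Upper integration limit (months); defaults to the last knot.
#' @return RMST in months.
#' @export
restricted_mean_survival <- function(curve, t_max = max(curve$times)) {
  stopifnot(inherits(curve, "survival_curve"), t_max > 0)
  integrate(function(x) survival_at_time(curve, x), 0, t_max,
            subdivisions = 500L, rel.tol = 1e-8)$value
}

#' Export a survival curve as a two-column tibble
#' @param x A `survival_curve`.
#' @param ... Unused.
#' @return Tibble with `time_months`, `survival_prob`.
#' @method tidy survival_curve
#' @export
tidy.survival_curve <- function(x, ...) {
  tibble::tibble(time_months = x$times, survival_prob = x$probs)
}

#' Write / read survival curves as CSV
#' @param curve A `survival_curve`.
#' @param path File path.
#' @return `path` (write) or a `survival_curve` (read).
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(tidy(curve), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  survival_curve(df$time_months, df$survival_prob)
}

#' Plot one or more survival curves
#'
#' @param object A `survival_curve`.
#' @param ... Further `survival_curve`s to overlay, optionally named.
#' @return A ggplot object.
#' @method autoplot survival_curve
#' @export
autoplot.survival_curve <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "survival_curve")]
  curves <- c(list(object), extra)
  nms <- names(curves)
  if (is.null(nms)) nms <- rep("", length(curves))
  nms[nms == ""] <- paste0("curve ", seq_along(curves))[nms == ""]
  df <- purrr::map2_dfr(curves, nms, function(cv, nm) {
    grid <- seq(0, max(cv$times), length.out = 200)
    tibble::tibble(patient = nm, time_months = grid,
                   survival_prob = survival_at_time(cv, grid))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_months, .data$survival_prob,
                                   colour = .data$patient)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
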