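#' Declare a covariate schema for a patient cohort
#'
#' A schema names every covariate the models will see and declares its type.
#' Continuous covariates are numeric (ages, classifier probability scores);
#' categorical covariates carry an explicit level set whose *first* level is
#' the reference level dropped during one-hot encoding.
#'
#' @param continuous Character vector of continuous covariate names.
#' @param categorical Named list; each element is the character vector of
#'   levels for that covariate, reference level first.
#' @return An object of class `cohort_schema`.
#' @examples
#' cohort_schema(
#'   continuous = "age",
#'   categorical = list(stage = c("I", "II", "III", "IV"))
#' )
#' @export
cohort_schema <- function(continuous = character(), categorical = list()) {
  stopifnot(is.character(continuous))
  if (length(categorical)) {
    if (is.null(names(categorical)) || any(names(categorical) == "")) {
      abort("every categorical covariate must be named")
    }
    ok <- vapply(categorical, function(l) is.character(l) && length(l) >= 2, logical(1))
    if (!all(ok)) abort("categorical levels must be character vectors of length >= 2")
  }
  dup <- intersect(continuous, names(categorical))
  if (length(dup)) abort(paste0("covariate declared twice: ", paste(dup, collapse = ", ")))
  structure(
    list(continuous = continuous, categorical = categorical),
    class = "cohort_schema"
  )
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("<cohort_schema>\n")
  cat("  continuous: ", paste(x$continuous, collapse = ", "), "\n")
  for (nm in names(x$categorical)) {
    cat("  ", nm, ": ", paste(x$categorical[[nm]], collapse = "/"),
        " (ref ", x$categorical[[nm]][1], ")\n", sep = "")
  }
  invisible(x)
}

schema_covariates <- function(schema) c(schema$continuous, names(schema$categorical))

#' Build a validated cohort table from a data frame
#'
#' Validates survival times, event indicators and schema covariates, dropping
#' (or, under `strict = TRUE`, failing on) unusable rows the way a
#' complete-case clinical analysis would. The number of dropped rows is kept
#' in the `dropped_count` attribute.
#'
#' @param data A data frame with columns `time_months`, `event`, optionally
#'   `id`, and one column per schema covariate.
#' @param schema A [cohort_schema()].
#' @param strict If `TRUE`, any invalid row (non-positive/non-finite time,
#'   event outside \{0, 1\}) is a fatal error naming the row; if `FALSE`
#'   (default) such rows and rows with missing covariates are dropped and
#'   counted.
#' @return A `cohort_table` tibble with attributes `schema` and
#'   `dropped_count`.
#' @export
as_cohort <- function(data, schema, strict = FALSE) {
  stopifnot(inherits(schema, "cohort_schema"))
  data <- tibble::as_tibble(data)
  needed <- c("time_months", "event", schema_covariates(schema))
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"id" %in% names(data)) data$id <- paste0("P", seq_len(nrow(data)))
  data$id <- as.character(data$id)

  bad_time <- !is.finite(suppressWarnings(as.numeric(data$time_months))) |
    suppressWarnings(as.numeric(data$time_months)) <= 0
  bad_event <- !(data$event %in% c(0, 1))
  if (strict && any(bad_time | bad_event, na.rm = TRUE)) {
    rows <- which(bad_time | bad_event)
    abort(paste0(
      "invalid time/event in row(s): ", paste(rows, collapse = ", "),
      " (time must be a positive finite number, event 0 or 1)"
    ))
  }
  incomplete <- !complete.cases(data[needed])
  drop <- incomplete | ifelse(is.na(bad_time), TRUE, bad_time) |
    ifelse(is.na(bad_event), TRUE, bad_event)
  dropped <- sum(drop)
  data <- data[!drop, , drop = FALSE]
  data$time_months <- as.numeric(data$time_months)
  data$event <- as.integer(data$event)

  for (nm in names(schema$categorical)) {
    lev <- schema$categorical[[nm]]
    vals <- as.character(data[[nm]])
    unseen <- setdiff(unique(vals), lev)
    if (length(unseen)) {
      abort(paste0("unseen level(s) for '", nm, "': ", paste(unseen, collapse = ", ")))
    }
    data[[nm]] <- factor(vals, levels = lev)
  }
  for (nm in schema$continuous) data[[nm]] <- as.numeric(data[[nm]])

  out <- data[c("id", "time_months", "event", schema_covariates(schema))]
  structure(out,
    class = c("cohort_table", class(tibble::tibble())),
    schema = schema, dropped_count = dropped
  )
}

#' Read a cohort CSV
#'
#' Reads a comma-separated patient table (header row; columns `time_months`,
#' `event`, covariates) and validates it against a schema via [as_cohort()].
#'
#' @inheritParams as_cohort
#' @param path Path to the CSV file.
#' @return A `cohort_table` tibble.
#' @export
read_cohort_csv <- function(path, schema, strict = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_cohort(raw, schema, strict = strict)
}

#' Write a cohort table to CSV
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (nm in names(out)) if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x), " patients, ", sum(x$event),
      " events (", attr(x, "dropped_count") %||% 0, " rows dropped at read)\n", sep = "")
  NextMethod()
}

#' Number of rows dropped during cohort validation
#' @param cohort A `cohort_table`.
#' @return Integer count.
#' @export
dropped_count <- function(cohort) attr(cohort, "dropped_count") %||% 0L

#' @export
`[.cohort_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    schema <- attr(x, "schema")
    need <- c("time_months", "event", schema_covariates(schema))
    if (all(need %in% names(out))) {
      attr(out, "schema") <- schema
    } else {
      # a column subset is no longer a valid cohort: fall back to a tibble
      class(out) <- setdiff(class(out), "cohort_table")
      attr(out, "schema") <- NULL
    }
  }
  out
}

#' Encode a cohort into a numeric design matrix
#'
#' Categorical covariates are one-hot encoded against their reference level
#' (a reference-level patient encodes as all zeros); continuous covariates are
#' optionally centred and scaled to unit sample variance (n - 1 denominator).
#' Column order is deterministic: schema order, then level order. Scaling
#' constants are stored so the same transform can be applied to held-out data
#' with [apply_design()], preventing train/test leakage.
#'
#' A constant continuous column under `standardize = TRUE` is flagged
#' (`zero_variance`) and left uncentred/unscaled.
#'
#' @param cohort A `cohort_table`.
#' @param standardize Centre/scale continuous covariates? Default `TRUE`.
#' @return A `covariate_design` with fields `X` (n x p matrix), `columns`,
#'   `center`, `scale`, `zero_variance`, `schema`, `standardize`.
#' @export
encode_design <- function(cohort, standardize = TRUE) {
  schema <- attr(cohort, "schema")
  stopifnot(inherits(schema, "cohort_schema"))
  blocks <- list(); centers <- numeric(); scales <- numeric(); zv <- character()

  for (nm in schema$continuous) {
    v <- cohort[[nm]]
    if (standardize) {
      s <- sd(v)
      if (!is.finite(s) || s == 0) {
        zv <- c(zv, nm)
        centers[nm] <- 0; scales[nm] <- 1
      } else {
        centers[nm] <- mean(v); scales[nm] <- s
        v <- (v - centers[nm]) / scales[nm]
      }
    } else {
      centers[nm] <- 0; scales[nm] <- 1
    }
    blocks[[nm]] <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
  }
  for (nm in names(schema$categorical)) {
    lev <- schema$categorical[[nm]]
    f <- factor(as.character(cohort[[nm]]), levels = lev)
    m <- vapply(lev[-1], function(l) as.numeric(f == l), numeric(nrow(cohort)))
    if (nrow(cohort) == 1) m <- matrix(m, nrow = 1)
    colnames(m) <- paste(nm, lev[-1], sep = "=")
    for (cn in colnames(m)) { centers[cn] <- 0; scales[cn] <- 1 }
    blocks[[nm]] <- m
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- NULL
  structure(
    list(
      X = X, columns = colnames(X),
      center = centers[colnames(X)], scale = scales[colnames(X)],
      zero_variance = zv, schema = schema, standardize = standardize
    ),
    class = "covariate_design"
  )
}

#' Apply a fitted design encoding to new data
#'
#' Encodes `cohort` (or a bare covariate data frame) with the column layout
#' and scaling constants learned by [encode_design()] on training data.
#' Unseen categorical levels are an error listing the offending level.
#'
#' @param design A `covariate_design`.
#' @param cohort A `cohort_table` or data frame holding the schema covariates.
#' @return An n x p numeric matrix with the design's columns.
#' @export
apply_design <- function(design, cohort) {
  stopifnot(inherits(design, "covariate_design"))
  schema <- design$schema
  n <- nrow(cohort)
  blocks <- list()
  for (nm in schema$continuous) {
    if (!nm %in% names(cohort)) abort(paste0("missing covariate '", nm, "'"))
    v <- (as.numeric(cohort[[nm]]) - design$center[nm]) / design$scale[nm]
    blocks[[nm]] <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
  }
  for (nm in names(schema$categorical)) {
    if (!nm %in% names(cohort)) abort(paste0("missing covariate '", nm, "'"))
    lev <- schema$categorical[[nm]]
    vals <- as.character(cohort[[nm]])
    unseen <- setdiff(unique(vals), lev)
    if (length(unseen)) {
      abort(paste0("unseen level(s) for '", nm, "': ", paste(unseen, collapse = ", ")))
    }
    f <- factor(vals, levels = lev)
    m <- vapply(lev[-1], function(l) as.numeric(f == l), numeric(n))
    if (n == 1) m <- matrix(m, nrow = 1)
    colnames(m) <- paste(nm, lev[-1], sep = "=")
    blocks[[nm]] <- m
  }
  X <- do.call(cbind, blocks)[, design$columns, drop = FALSE]
  rownames(X) <- NULL
  X
}

#' Invert the standardization of a design matrix
#'
#' Maps encoded columns back to the raw covariate scale using the stored
#' constants; the round-trip with [apply_design()] is exact to machine
#' precision.
#'
#' @param design A `covariate_design`.
#' @param X Encoded matrix with the design's columns.
#' @return Matrix on the raw scale.
#' @export
invert_design <- function(design, X) {
  sweep(sweep(X, 2, design$scale[colnames(X)], `*`), 2,
        design$center[colnames(X)], `+`)
}

#' Stratified k-fold cross-validation split
#'
#' Partitions patient indices into k folds stratified by event indicator, so
#' each fold's event proportion is within one patient of the overall
#' proportion. Deterministic for a given seed.
#'
#' @param cohort A `cohort_table` (or any data frame with an `event` column).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of k elements, each `list(train =, test =)` of row indices;
#'   test sets partition `1:nrow(cohort)` exactly.
#' @export
stratified_kfold_split <- function(cohort, k = 5, seed = 1) {
  n <- nrow(cohort)
  if (k < 2) abort("k must be >= 2")
  if (k > n) abort("k exceeds the number of patients")
  event <- as.integer(cohort$event)
  fold <- integer(n)
  set.seed(seed)
  for (s in unique(event)) {
    idx <- sample(which(event == s))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}
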