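#' Transform a left-skewed 0-100 test score
#'
#' Cognitive screening scores (such as the 0-100 Modified Mini-Mental State
#' Examination) cluster near the top of their range; the transform
#' `-ln(101 - score)` spreads out the upper tail while remaining strictly
#' increasing, so higher transformed values still mean better scores.
#'
#' @param score numeric vector of scores, each strictly less than 101.
#' @return `-log(101 - score)`.
#' @examples
#' transform_left_skew(c(0, 94, 100))
#' @export
transform_left_skew <- function(score) {
  score <- as.numeric(score)
  if (any(score >= 101, na.rm = TRUE)) {
    stop("scores must be strictly less than 101")
  }
  -log(101 - score)
}

#' Preprocessing configuration
#'
#' @param outcome_transform `"none"` or `"left_skew_3ms"` (apply
#'   [transform_left_skew()] to the outcome column).
#' @param log_columns character vector of predictor columns replaced by
#'   their natural logarithm (used for right-skewed volumes such as the
#'   pallidum).
#' @param influential_threshold absolute externally studentized residual
#'   above which a row is treated as influential (default 2.5).
#' @param condition_number_limit condition number above which the design is
#'   flagged as seriously multicollinear (default 100).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(outcome_transform = c("none", "left_skew_3ms"),
                              log_columns = character(),
                              influential_threshold = 2.5,
                              condition_number_limit = 100) {
  outcome_transform <- match.arg(outcome_transform)
  stopifnot(influential_threshold > 0, condition_number_limit > 0)
  structure(list(outcome_transform = outcome_transform,
                 log_columns = as.character(log_columns),
                 influential_threshold = influential_threshold,
                 condition_number_limit = condition_number_limit),
            class = "preprocess_config")
}

#' Remove influential observations by single-predictor screening
#'
#' Each predictor is regressed on its own (with intercept) against the
#' outcome, and the externally studentized residuals of that simple fit
#' are computed — the residual divided by an error standard deviation
#' estimated with the observation itself deleted. Any row whose residual
#' exceeds `threshold` in absolute value in *any* of the single-predictor
#' fits is removed, once, jointly. Constant predictors are skipped with a
#' warning.
#'
#' @param data an [spls_dataset].
#' @param threshold positive cutoff on `|r_i|` (default 2.5).
#' @return list with `data` (the filtered [spls_dataset]) and `report`, a
#'   data frame of removals (`row`, `predictor`, `residual`) plus the
#'   attribute-like fields `rows_remaining` and `removed_rows` stored
#'   alongside it in a `filter_report` list.
#' @export
influential_filter <- function(data, threshold = 2.5) {
  stopifnot(inherits(data, "spls_dataset"), threshold > 0)
  n <- nrow(data$X)
  if (n < 4L) stop("externally studentized residuals need at least 4 rows")
  removed <- integer()
  records <- list()
  for (j in seq_len(ncol(data$X))) {
    x <- data$X[, j]
    if (stats::sd(x) == 0) {
      warning("skipping constant predictor ", data$names[j])
      next
    }
    fit <- stats::lm(data$y ~ x)
    sigma <- sqrt(sum(stats::resid(fit)^2) / fit$df.residual)
    if (sigma < 1e-10 * max(1, stats::sd(data$y))) {
      next  # numerically exact fit: all residuals are zero
    }
    r <- stats::rstudent(fit)
    flag <- which(is.finite(r) & abs(r) > threshold)
    if (length(flag)) {
      removed <- union(removed, flag)
      records[[length(records) + 1L]] <-
        data.frame(row = flag, predictor = data$names[j],
                   residual = unname(r[flag]))
    }
  }
  removed <- sort(removed)
  keep <- setdiff(seq_len(n), removed)
  report <- structure(list(
    removed_rows = removed,
    records = if (length(records)) do.call(rbind, records) else
      data.frame(row = integer(), predictor = character(),
                 residual = numeric()),
    rows_remaining = length(keep)), class = "filter_report")
  filtered <- spls_dataset(data$X[keep, , drop = FALSE], data$y[keep],
                           names = data$names, force_in = data$force_in)
  list(data = filtered, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Influential-point filter: removed ", length(x$removed_rows),
      " row(s), ", x$rows_remaining, " remaining\n", sep = "")
  if (nrow(x$records)) print(x$records)
  invisible(x)
}

#' Condition number of a design matrix
#'
#' Computes the ratio of the largest to the smallest singular value of the
#' column-equilibrated design: each column (including an intercept column,
#' by default) is scaled to unit Euclidean norm before the singular values
#' are taken. This is the Belsley collinearity diagnostic; values above
#' `limit` (conventionally 100) indicate serious multicollinearity.
#'
#' @param X numeric matrix with more rows than columns.
#' @param add_intercept prepend a column of ones before equilibration
#'   (default `TRUE`).
#' @param limit flagging threshold (default 100).
#' @return list with `value` (the condition number; `Inf` when the design
#'   is exactly singular) and `exceeds_limit`.
#' @examples
#' condition_number(diag(5), add_intercept = FALSE)
#' @export
condition_number <- function(X, add_intercept = TRUE, limit = 100) {
  X <- as.matrix(X)
  if (add_intercept) X <- cbind(1, X)
  if (nrow(X) < ncol(X)) stop("need at least as many rows as columns")
  norms <- sqrt(colSums(X^2))
  if (any(norms == 0)) {
    return(list(value = Inf, exceeds_limit = TRUE))
  }
  d <- svd(sweep(X, 2L, norms, "/"), nu = 0, nv = 0)$d
  value <- if (min(d) <= .Machine$double.eps * max(d)) Inf else max(d) / min(d)
  list(value = value, exceeds_limit = value > limit)
}

#' Read a modelling dataset from CSV
#'
#' Reads a header-row CSV of numeric columns, designates one column as the
#' outcome, applies the configured transforms (outcome transform, natural
#' log of selected predictors), drops rows with missing values (with a
#' message giving the count), and resolves force-in predictors by name.
#'
#' @param path CSV file path.
#' @param outcome_name name of the outcome column.
#' @param force_in_names character vector of predictor columns kept in
#'   every model.
#' @param config a [preprocess_config].
#' @return an [spls_dataset].
#' @export
read_dataset <- function(path, outcome_name, force_in_names = character(),
                         config = preprocess_config()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!outcome_name %in% names(df)) {
    stop("outcome column '", outcome_name, "' not found in ", path)
  }
  unknown <- setdiff(c(force_in_names, config$log_columns), names(df))
  if (length(unknown)) {
    stop("unknown column name(s): ", paste(unknown, collapse = ", "))
  }
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[cn]])))) &
                     !is.na(df[[cn]]))[1L]
      stop("non-numeric value in column '", cn, "', row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  complete <- stats::complete.cases(df)
  if (any(!complete)) {
    message("dropping ", sum(!complete), " row(s) with missing values")
    df <- df[complete, , drop = FALSE]
  }
  y <- df[[outcome_name]]
  if (config$outcome_transform == "left_skew_3ms") {
    y <- transform_left_skew(y)
  }
  X <- as.matrix(df[setdiff(names(df), outcome_name)])
  for (cn in intersect(config$log_columns, colnames(X))) {
    if (any(X[, cn] <= 0)) stop("cannot log-transform non-positive column '",
                                cn, "'")
    X[, cn] <- log(X[, cn])
  }
  spls_dataset(X, y, force_in = as.character(force_in_names))
}

#' Write a dataset back to CSV
#'
#' Writes predictors plus the outcome column (named `outcome_name`) as a
#' header-row CSV, preserving values to full precision.
#'
#' @param data an [spls_dataset].
#' @param path output file path.
#' @param outcome_name column name for the outcome (default `"y"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, outcome_name = "y") {
  stopifnot(inherits(data, "spls_dataset"))
  df <- as.data.frame(data$X)
  df[[outcome_name]] <- data$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
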