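#' Bundle a predictor matrix and outcome into a modelling dataset
#'
#' Creates the container used by every fitting routine in the package: a
#' numeric predictor matrix, a continuous outcome, predictor names, and an
#' optional set of "force-in" predictors (confounders such as age, sex or
#' total gray matter volume) that are kept in every model regardless of the
#' sparsity penalty.
#'
#' @param X numeric matrix or data frame, subjects in rows, predictors in
#'   columns. Column names are used as predictor labels when present.
#' @param y numeric outcome vector, one value per row of `X`.
#' @param names optional character vector of predictor labels; defaults to
#'   `colnames(X)` or `x1..xp`.
#' @param force_in integer or character vector identifying predictors that
#'   must appear in every fitted model (never removed by the sparsity step).
#'
#' @return An object of class `spls_dataset` with components `X`, `y`,
#'   `names` and `force_in` (integer column indices).
#' @examples
#' d <- spls_dataset(matrix(rnorm(60), 20, 3), rnorm(20))
#' d
#' @export
spls_dataset <- function(X, y, names = NULL, force_in = integer()) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("`X` must be a numeric matrix or data frame")
  }
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length of `y` (", length(y),
                           ") does not match nrow(X) (", n, ")")
  if (n < 3L) stop("at least 3 observations are required")
  if (p < 1L) stop("at least one predictor is required")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed; drop or impute them first")
  if (is.null(names)) {
    names <- colnames(X)
    if (is.null(names)) names <- paste0("x", seq_len(p))
  }
  names <- as.character(names)
  if (length(names) != p) stop("`names` must have one label per predictor")
  if (anyDuplicated(names)) stop("predictor names must be unique")
  if (is.character(force_in)) {
    miss <- setdiff(force_in, names)
    if (length(miss)) stop("unknown force-in predictor(s): ",
                           paste(miss, collapse = ", "))
    force_in <- match(force_in, names)
  }
  force_in <- sort(unique(as.integer(force_in)))
  if (length(force_in) && (min(force_in) < 1L || max(force_in) > p)) {
    stop("`force_in` indices must lie in 1..", p)
  }
  colnames(X) <- names
  structure(list(X = X, y = y, names = names, force_in = force_in),
            class = "spls_dataset")
}

#' @export
print.spls_dataset <- function(x, ...) {
  cat("spls_dataset: ", nrow(x$X), " observations, ", ncol(x$X),
      " predictors\n", sep = "")
  if (length(x$force_in)) {
    cat("force-in: ", paste(x$names[x$force_in], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
dim.spls_dataset <- function(x) dim(x$X)

#' Center and scale columns to mean zero and unit sample variance
#'
#' Standardizes each column of a matrix (or a single vector) using the
#' sample standard deviation (denominator n - 1), returning the scaling
#' constants so the transform can be inverted.
#'
#' @param values numeric matrix or vector.
#' @return list with `values` (standardized matrix/vector), `center`
#'   (per-column means) and `scale` (per-column sample SDs).
#' @examples
#' standardize_columns(c(1, 2, 3))
#' @export
standardize_columns <- function(values) {
  vec <- is.null(dim(values))
  m <- if (vec) matrix(as.numeric(values), ncol = 1L) else as.matrix(values)
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  bad <- which(scale == 0 | !is.finite(scale))
  if (length(bad)) {
    lab <- colnames(m)[bad]
    if (is.null(lab)) lab <- as.character(bad)
    stop("constant column(s) cannot be standardized: ",
         paste(lab, collapse = ", "))
  }
  out <- sweep(sweep(m, 2L, center, "-"), 2L, scale, "/")
  if (vec) out <- drop(out)
  list(values = out, center = center, scale = scale)
}
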