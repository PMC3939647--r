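#' Fit sparse PLS over every (K, eta) cell of a tuning grid
#'
#' The exhaustive-grid procedure: one sparse PLS model is fitted for every
#' combination of the number of components `K` and the sparsity `eta`, and
#' the full standardized coefficient vector of every cell is stored. The
#' fitting loop has no randomness, so the result is deterministic given the
#' data. Because the SPLS iteration for `K` components passes through the
#' same states as the first `K` steps of a longer run, each eta value is
#' computed in a single pass over `max(k_grid)` steps.
#'
#' @param data an [spls_dataset].
#' @param k_grid integer vector of component numbers (default `1:p`, capped
#'   at `n - 2`).
#' @param eta_grid numeric vector of sparsity values in `[0, 1)` (default
#'   `seq(0.1, 0.9, by = 0.1)`).
#' @return An object of class `spls_grid` with `k_grid`, `eta_grid`,
#'   `coef` (a p x |k_grid| x |eta_grid| array of standardized
#'   coefficients) and the predictor `names` / `force_in` of the data.
#' @examples
#' d <- spls_dataset(matrix(rnorm(200), 50, 4), rnorm(50))
#' g <- run_grid(d, k_grid = 1:3)
#' selection_summary(g)
#' @export
run_grid <- function(data, k_grid = NULL, eta_grid = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(data, "spls_dataset"))
  n <- nrow(data$X)
  p <- ncol(data$X)
  if (is.null(k_grid)) k_grid <- seq_len(min(p, n - 2L))
  k_grid <- sort(unique(as.integer(k_grid)))
  eta_grid <- sort(unique(as.numeric(eta_grid)))
  if (!length(k_grid) || !length(eta_grid)) stop("grids must be non-empty")
  if (min(k_grid) < 1L || max(k_grid) > min(p, n - 1L)) {
    stop("`k_grid` must lie in 1..min(p, n - 1)")
  }
  if (min(eta_grid) < 0 || max(eta_grid) >= 1) {
    stop("`eta_grid` values must lie in [0, 1)")
  }
  sx <- standardize_columns(data$X)
  sy <- standardize_columns(data$y)
  kmax <- max(k_grid)
  coefs <- array(0, dim = c(p, length(k_grid), length(eta_grid)),
                 dimnames = list(data$names, paste0("K", k_grid),
                                 paste0("eta", format(eta_grid))))
  for (j in seq_along(eta_grid)) {
    st <- tryCatch(
      spls_steps(sx$values, sy$values, kmax, eta_grid[j], data$force_in,
                 record = TRUE),
      error = function(e) stop("grid cell (K <= ", kmax, ", eta = ",
                               eta_grid[j], ") failed to fit: ",
                               conditionMessage(e)))
    coefs[, , j] <- st$betas[, k_grid, drop = FALSE]
  }
  structure(list(k_grid = k_grid, eta_grid = eta_grid, coef = coefs,
                 names = data$names, force_in = data$force_in),
            class = "spls_grid")
}

#' @export
print.spls_grid <- function(x, ...) {
  cat("All-possible SPLS grid: ", length(x$k_grid), " K values x ",
      length(x$eta_grid), " eta values = ",
      length(x$k_grid) * length(x$eta_grid), " models, ",
      length(x$names), " predictors\n", sep = "")
  invisible(x)
}

#' Per-predictor selection frequency and average non-zero coefficient
#'
#' Summarizes an exhaustive grid run: for each predictor, the percentage of
#' grid cells in which its coefficient was non-zero ("percent chosen"), and
#' the average of its standardized coefficient over only those cells. A
#' predictor never selected gets `NA` for the average (zero would misstate
#' its effect size). Predictors are ranked by percent chosen, breaking ties
#' by the magnitude of the average non-zero coefficient, then by name.
#'
#' @param grid an `spls_grid` from [run_grid()].
#' @return A data frame with one row per predictor, ordered by rank:
#'   `predictor`, `percent_chosen` (in `[0, 100]`), `mean_nonzero_beta`,
#'   `rank`.
#' @export
selection_summary <- function(grid) {
  stopifnot(inherits(grid, "spls_grid"))
  p <- length(grid$names)
  ncell <- length(grid$k_grid) * length(grid$eta_grid)
  flat <- matrix(grid$coef, nrow = p)   # p x ncell
  nonzero <- flat != 0
  chosen <- rowSums(nonzero)
  percent <- 100 * chosen / ncell
  sums <- rowSums(flat)                 # zeros contribute nothing
  mean_nz <- ifelse(chosen > 0, sums / chosen, NA_real_)
  ord <- order(-percent, -abs(mean_nz), grid$names, na.last = TRUE)
  out <- data.frame(predictor = grid$names[ord],
                    percent_chosen = percent[ord],
                    mean_nonzero_beta = mean_nz[ord],
                    rank = seq_len(p),
                    row.names = NULL)
  class(out) <- c("selection_summary", "data.frame")
  out
}

#' @export
summary.spls_grid <- function(object, ...) selection_summary(object)

#' Write a selection summary as TSV
#'
#' @param x a `selection_summary` data frame.
#' @param path output file path. Never-chosen predictors are written with
#'   `NA` in the `mean_nonzero_beta` column.
#' @return `path`, invisibly.
#' @export
write_selection_summary <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
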