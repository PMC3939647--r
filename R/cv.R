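#' Cross-validated mean squared prediction error over a tuning grid
#'
#' The traditional tuning procedure: for every `(K, eta)` pair the data are
#' split into `v` folds, the model is fitted on `v - 1` folds and used to
#' predict the held-out fold, and the squared errors over all held-out rows
#' are averaged. Leave-one-out (`folds = "loo"` or `folds = n`) is
#' deterministic; any smaller fold count shuffles rows under `seed`, which
#' is why k-fold tuning is seed-sensitive (see [seed_sensitivity()]).
#'
#' `K` values exceeding the bound `min(p, (v - 1) * n / v)` are dropped
#' with a warning.
#'
#' @param data an [spls_dataset].
#' @param k_grid integer vector of candidate component numbers.
#' @param eta_grid numeric vector of candidate sparsity values.
#' @param folds integer fold count `v >= 2`, or `"loo"` for leave-one-out.
#' @param seed integer seed for the fold assignment (ignored for LOO).
#' @return An object of class `mspe_grid`: `mspe` (matrix, rows = K,
#'   columns = eta), `k_grid`, `eta_grid`, `folds`, `seed`, and `optimal`,
#'   the minimizing pair as chosen by [select_optimal()].
#' @examples
#' d <- spls_dataset(matrix(rnorm(200), 50, 4), rnorm(50))
#' cv <- cv_mspe(d, k_grid = 1:3, eta_grid = c(0.3, 0.6), folds = 5, seed = 1)
#' cv$optimal
#' @export
cv_mspe <- function(data, k_grid = NULL, eta_grid = seq(0.1, 0.9, by = 0.1),
                    folds = "loo", seed = NULL) {
  stopifnot(inherits(data, "spls_dataset"))
  n <- nrow(data$X)
  p <- ncol(data$X)
  loo <- identical(folds, "loo") || (is.numeric(folds) && folds == n)
  v <- if (loo) n else as.integer(folds)
  if (v < 2L) stop("`folds` must be at least 2 (or \"loo\")")
  if (v > n) stop("`folds` cannot exceed the number of observations")
  kbound <- floor(min(p, (v - 1) * n / v))
  if (is.null(k_grid)) k_grid <- seq_len(kbound)
  k_grid <- sort(unique(as.integer(k_grid)))
  drop_k <- k_grid > kbound
  if (any(drop_k)) {
    warning("dropping K values above the bound min(p, (v-1)n/v) = ", kbound,
            ": ", paste(k_grid[drop_k], collapse = ", "))
    k_grid <- k_grid[!drop_k]
  }
  if (!length(k_grid)) stop("no admissible K values remain")
  eta_grid <- sort(unique(as.numeric(eta_grid)))

  # fold assignment: random permutation, then contiguous blocks of
  # near-equal size; LOO needs no randomness
  if (loo) {
    assignment <- seq_len(n)
  } else {
    if (!is.null(seed)) {
      assignment <- withr::with_seed(seed, sample.int(n))
    } else {
      assignment <- sample.int(n)
    }
    assignment <- sort(rep_len(seq_len(v), n))[order(assignment)]
  }

  kmax <- max(k_grid)
  se <- array(0, dim = c(n, length(k_grid), length(eta_grid)))
  for (f in seq_len(v)) {
    test <- which(assignment == f)
    train <- setdiff(seq_len(n), test)
    if (length(train) < 2L) stop("fold ", f, " leaves fewer than 2 training rows")
    sx <- standardize_columns(data$X[train, , drop = FALSE])
    sy <- standardize_columns(data$y[train])
    Xt <- sweep(sweep(data$X[test, , drop = FALSE], 2L, sx$center, "-"),
                2L, sx$scale, "/")
    for (j in seq_along(eta_grid)) {
      st <- spls_steps(sx$values, sy$values, kmax, eta_grid[j],
                       data$force_in, record = TRUE)
      pred <- sy$center + sy$scale *
        (Xt %*% st$betas[, k_grid, drop = FALSE])   # |test| x |k_grid|
      se[test, , j] <- (pred - data$y[test])^2
    }
  }
  mspe <- apply(se, c(2L, 3L), mean)
  dimnames(mspe) <- list(paste0("K", k_grid), paste0("eta", format(eta_grid)))
  out <- structure(list(k_grid = k_grid, eta_grid = eta_grid, mspe = mspe,
                        folds = if (loo) "loo" else v, seed = seed),
                   class = "mspe_grid")
  out$optimal <- select_optimal(out)
  out
}

#' @export
print.mspe_grid <- function(x, ...) {
  cat("Cross-validated MSPE grid (",
      if (identical(x$folds, "loo")) "leave-one-out" else
        paste0(x$folds, "-fold"), ")\n", sep = "")
  print(round(x$mspe, 4))
  cat("optimal: K = ", x$optimal$K, ", eta = ", format(x$optimal$eta),
      "\n", sep = "")
  invisible(x)
}

#' Pick the tuning pair minimizing cross-validated error
#'
#' Returns the `(K, eta)` cell with the smallest MSPE. Ties are broken in
#' favour of the smaller `K`, then the larger `eta` — the most parsimonious
#' model among the tied cells.
#'
#' @param grid an `mspe_grid` from [cv_mspe()].
#' @return list with elements `K`, `eta` and `mspe`.
#' @export
select_optimal <- function(grid) {
  stopifnot(inherits(grid, "mspe_grid"))
  m <- grid$mspe
  if (!all(is.finite(m))) stop("MSPE grid contains non-finite values")
  best <- which(m == min(m), arr.ind = TRUE)
  # ties: smallest K, then largest eta
  best <- best[order(best[, 1L], -best[, 2L]), , drop = FALSE]
  i <- best[1L, 1L]; j <- best[1L, 2L]
  list(K = grid$k_grid[i], eta = grid$eta_grid[j], mspe = m[i, j])
}

#' How often each tuning pair wins the cross-validation, across seeds
#'
#' Re-runs k-fold tuning under many fold-assignment seeds and tallies which
#' `(K, eta)` pair is selected each time. With k-fold (as opposed to LOO)
#' cross-validation the winning pair can change with the seed; a diffuse
#' tally is a warning sign that a single "optimal" pair is unstable and
#' that leave-one-out tuning, or the exhaustive-grid summary of
#' [run_grid()], should be preferred.
#'
#' @param data an [spls_dataset].
#' @param k_grid,eta_grid candidate grids, as in [cv_mspe()].
#' @param v fold count (must be less than `n`; the diagnostic is vacuous
#'   for LOO).
#' @param n_seeds number of fold-assignment seeds to try.
#' @param base_seed integer; the individual seeds are drawn reproducibly
#'   from this.
#' @return An object of class `seed_sensitivity` : a data frame `counts`
#'   with columns `K`, `eta`, `count` sorted by decreasing count, plus
#'   `n_seeds`.
#' @export
seed_sensitivity <- function(data, k_grid = NULL,
                             eta_grid = seq(0.1, 0.9, by = 0.1),
                             v = 10, n_seeds = 100, base_seed = 1) {
  stopifnot(inherits(data, "spls_dataset"))
  if (v >= nrow(data$X)) stop("`v` must be less than n; use k-fold CV here")
  seeds <- withr::with_seed(base_seed,
                            sample.int(.Machine$integer.max, n_seeds))
  picks <- vapply(seeds, function(s) {
    opt <- suppressWarnings(
      cv_mspe(data, k_grid, eta_grid, folds = v, seed = s))$optimal
    c(opt$K, opt$eta)
  }, numeric(2))
  tab <- stats::aggregate(list(count = rep(1L, n_seeds)),
                          by = list(K = picks[1L, ], eta = picks[2L, ]),
                          FUN = sum)
  tab <- tab[order(-tab$count, tab$K, -tab$eta), , drop = FALSE]
  row.names(tab) <- NULL
  structure(list(counts = tab, n_seeds = n_seeds, v = v,
                 base_seed = base_seed),
            class = "seed_sensitivity")
}

#' @export
print.seed_sensitivity <- function(x, ...) {
  cat("Tuning-pair selection across ", x$n_seeds, " fold-assignment seeds (",
      x$v, "-fold CV):\n", sep = "")
  print(x$counts)
  invisible(x)
}
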