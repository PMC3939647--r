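#' Specification of the block-collinear simulation design
#'
#' Describes the data-generating process used throughout the package's
#' simulation study: predictors come in blocks that share a latent mean
#' vector, making them strongly collinear within a block, and the outcome
#' is a linear combination of the block means plus noise. With the default
#' settings there are three blocks — `S1` (predictors 1–7) strongly
#' associated with the outcome, `S2` (8–17) weakly and negatively
#' associated, and `S3` (18–27) not associated — and the within-block
#' population correlation is `20/21` (about 0.95).
#'
#' @param n sample size (default 100).
#' @param breakpoints block boundaries `(c0, ..., cB)`; block `j` holds
#'   predictors `c(j-1)+1 .. c(j)`. Default `c(0, 7, 17, 27)`.
#' @param block_mean_variance variance of the shared latent block means
#'   (default 20).
#' @param predictor_noise_variance variance of the predictor-specific noise
#'   (default 1).
#' @param outcome_coefficients one coefficient per block applied to the
#'   latent means when forming the outcome (default `c(2, -0.2, 0)`).
#' @param outcome_noise_variance variance of the outcome noise (default 1).
#' @return An object of class `simulation_spec`.
#' @examples
#' spec <- simulation_spec()
#' d <- generate_dataset(spec, seed = 1)
#' dim(d)
#' @export
simulation_spec <- function(n = 100,
                            breakpoints = c(0, 7, 17, 27),
                            block_mean_variance = 20,
                            predictor_noise_variance = 1,
                            outcome_coefficients = c(2, -0.2, 0),
                            outcome_noise_variance = 1) {
  breakpoints <- as.numeric(breakpoints)
  if (breakpoints[1L] != 0 || any(diff(breakpoints) <= 0)) {
    stop("`breakpoints` must start at 0 and be strictly increasing")
  }
  nblock <- length(breakpoints) - 1L
  if (length(outcome_coefficients) != nblock) {
    stop("need one outcome coefficient per block (", nblock, ")")
  }
  stopifnot(n >= 3, block_mean_variance > 0, predictor_noise_variance >= 0,
            outcome_noise_variance >= 0)
  structure(list(n = as.integer(n), breakpoints = breakpoints,
                 block_mean_variance = block_mean_variance,
                 predictor_noise_variance = predictor_noise_variance,
                 outcome_coefficients = outcome_coefficients,
                 outcome_noise_variance = outcome_noise_variance),
            class = "simulation_spec")
}

#' Which block does each predictor belong to?
#'
#' @param spec a [simulation_spec].
#' @return integer vector of block labels, one per predictor.
#' @export
block_membership <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  p <- spec$breakpoints[length(spec$breakpoints)]
  findInterval(seq_len(p), spec$breakpoints, left.open = TRUE)
}

#' Draw one dataset from the block-collinear design
#'
#' For each block `j` a latent mean vector `m_j` of length `n` is drawn
#' from `N(0, block_mean_variance * I)`; each predictor in the block is
#' `m_j` plus independent `N(0, predictor_noise_variance * I)` noise; the
#' outcome is `sum_j coef_j * m_j` plus `N(0, outcome_noise_variance * I)`
#' noise. All predictor columns and the outcome are then standardized.
#'
#' @param spec a [simulation_spec].
#' @param seed integer seed; the draw is reproducible given `(spec, seed)`.
#' @return an [spls_dataset] with standardized `X` (n x p) and `y`.
#' @export
generate_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  draw <- function() {
    n <- spec$n
    nblock <- length(spec$breakpoints) - 1L
    p <- spec$breakpoints[length(spec$breakpoints)]
    M <- matrix(stats::rnorm(n * nblock, sd = sqrt(spec$block_mean_variance)),
                n, nblock)
    X <- matrix(0, n, p)
    blocks <- block_membership(spec)
    for (i in seq_len(p)) {
      X[, i] <- M[, blocks[i]] +
        stats::rnorm(n, sd = sqrt(spec$predictor_noise_variance))
    }
    y <- drop(M %*% spec$outcome_coefficients) +
      stats::rnorm(n, sd = sqrt(spec$outcome_noise_variance))
    spls_dataset(standardize_columns(X)$values,
                 standardize_columns(y)$values)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# One reproducible sub-seed per replicate so results do not depend on the
# order in which replicates are processed.
replicate_seeds <- function(base_seed, D) {
  withr::with_seed(base_seed, sample.int(.Machine$integer.max, D))
}

#' Average per-block selection percentage at every grid cell
#'
#' The selection-surface experiment: draw `D` replicate datasets from the
#' design, run the exhaustive `(K, eta)` grid on each, and record for every
#' cell the percentage of each block's predictors that received a non-zero
#' coefficient, averaged over replicates. The surfaces show how sparsity
#' (small `K`, large `eta`) prunes weakly and non-associated predictors
#' while strongly associated ones survive everywhere.
#'
#' @param spec a [simulation_spec].
#' @param D number of replicate datasets.
#' @param k_grid,eta_grid tuning grids, as in [run_grid()]; defaults
#'   `1:p` and `seq(0.1, 0.9, by = 0.1)`.
#' @param base_seed integer seed; replicate `r` uses an independent
#'   sub-seed derived from `(base_seed, r)`.
#' @return An object of class `selection_surface`: a list `surface` with
#'   one |k_grid| x |eta_grid| matrix of percentages per block (names
#'   `S1`, `S2`, ...), plus the grids and `D`.
#' @export
selection_surface <- function(spec, D = 50, k_grid = NULL,
                              eta_grid = seq(0.1, 0.9, by = 0.1),
                              base_seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"), D >= 1)
  p <- spec$breakpoints[length(spec$breakpoints)]
  if (is.null(k_grid)) k_grid <- seq_len(p)
  blocks <- block_membership(spec)
  nblock <- max(blocks)
  seeds <- replicate_seeds(base_seed, D)
  acc <- replicate(nblock,
                   matrix(0, length(k_grid), length(eta_grid)),
                   simplify = FALSE)
  for (r in seq_len(D)) {
    g <- run_grid(generate_dataset(spec, seeds[r]), k_grid, eta_grid)
    nz <- g$coef != 0                       # p x |K| x |eta|
    for (b in seq_len(nblock)) {
      sel <- apply(nz[blocks == b, , , drop = FALSE], c(2L, 3L), mean)
      acc[[b]] <- acc[[b]] + 100 * sel
    }
  }
  surface <- lapply(acc, function(m) {
    m <- m / D
    dimnames(m) <- list(paste0("K", k_grid),
                        paste0("eta", format(sort(unique(eta_grid)))))
    m
  })
  names(surface) <- paste0("S", seq_len(nblock))
  structure(list(surface = surface, k_grid = k_grid,
                 eta_grid = sort(unique(eta_grid)), D = D,
                 base_seed = base_seed),
            class = "selection_surface")
}

#' @export
print.selection_surface <- function(x, ...) {
  cat("Selection surfaces over ", x$D, " replicates (",
      length(x$k_grid), " x ", length(x$eta_grid), " grid)\n", sep = "")
  for (b in names(x$surface)) {
    cat(b, ": mean ", round(mean(x$surface[[b]]), 1), "%, min ",
        round(min(x$surface[[b]]), 1), "%\n", sep = "")
  }
  invisible(x)
}

#' Long-run per-predictor summary of all-possible SPLS
#'
#' The Monte-Carlo companion of [selection_summary()]: draw `D` replicate
#' datasets, run the exhaustive grid and its per-predictor summary on each,
#' and average both the percent-chosen and the mean non-zero standardized
#' coefficient across replicates. Replicates where a predictor was never
#' chosen contribute nothing to its coefficient average.
#'
#' @inheritParams selection_surface
#' @param D number of replicate datasets (default 100).
#' @return An object of class `long_run_summary`: a data frame `summary`
#'   with columns `predictor`, `block`, `avg_percent_chosen`,
#'   `avg_mean_nonzero_beta`, ordered by block then decreasing percent,
#'   plus `D`, the grids and `base_seed`.
#' @export
long_run_experiment <- function(spec, D = 100, k_grid = NULL,
                                eta_grid = seq(0.1, 0.9, by = 0.1),
                                base_seed = 1) {
  stopifnot(inherits(spec, "simulation_spec"), D >= 1)
  p <- spec$breakpoints[length(spec$breakpoints)]
  if (is.null(k_grid)) k_grid <- seq_len(p)
  blocks <- block_membership(spec)
  seeds <- replicate_seeds(base_seed, D)
  pct <- matrix(NA_real_, p, D)
  est <- matrix(NA_real_, p, D)
  for (r in seq_len(D)) {
    g <- run_grid(generate_dataset(spec, seeds[r]), k_grid, eta_grid)
    s <- selection_summary(g)
    i <- match(paste0("x", seq_len(p)), s$predictor)
    pct[, r] <- s$percent_chosen[i]
    est[, r] <- s$mean_nonzero_beta[i]
  }
  df <- data.frame(predictor = paste0("x", seq_len(p)),
                   block = paste0("S", blocks),
                   avg_percent_chosen = rowMeans(pct),
                   avg_mean_nonzero_beta = rowMeans(est, na.rm = TRUE))
  df <- df[order(df$block, -df$avg_percent_chosen), , drop = FALSE]
  row.names(df) <- NULL
  structure(list(summary = df, D = D, k_grid = k_grid,
                 eta_grid = sort(unique(eta_grid)), base_seed = base_seed),
            class = "long_run_summary")
}

#' @export
print.long_run_summary <- function(x, ...) {
  cat("Long-run all-possible SPLS summary over ", x$D, " replicates\n",
      sep = "")
  df <- x$summary
  df$avg_percent_chosen <- round(df$avg_percent_chosen, 2)
  df$avg_mean_nonzero_beta <- signif(df$avg_mean_nonzero_beta, 3)
  print(df)
  invisible(x)
}
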