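#' Soft-thresholded direction vector
#'
#' Applies the thresholding rule that creates sparsity in each latent
#' direction: components of `z` smaller in magnitude than `eta` times the
#' largest magnitude are set to exactly zero, and the survivors are shrunk
#' by that threshold. At `eta = 0` the vector is returned unchanged; as
#' `eta` approaches 1 only the component(s) attaining the maximum survive.
#'
#' @param z numeric vector (typically the predictor-outcome covariances
#'   `t(X) %*% r` for the current residual `r`).
#' @param eta sparsity parameter in `[0, 1)`.
#' @return numeric vector `w` with
#'   `w_i = sign(z_i) * max(0, |z_i| - eta * max(|z|))`.
#' @examples
#' soft_threshold_direction(c(2, -1, 0.5), eta = 0.6)
#' @export
soft_threshold_direction <- function(z, eta) {
  z <- as.numeric(z)
  if (length(z) == 0L || all(z == 0)) {
    stop("`z` is all zero: no direction exists")
  }
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0 || eta >= 1) {
    stop("`eta` must be a single value in [0, 1)")
  }
  az <- abs(z)
  thr <- eta * max(az)
  w <- sign(z) * pmax(0, az - thr)
  if (all(w == 0)) {
    # floating-point cancellation can zero everything at eta close to 1;
    # keep the dominant component so the algorithm can progress
    i <- which.max(az)
    w[i] <- sign(z[i]) * (az[i] - thr)
    if (w[i] == 0) w[i] <- sign(z[i]) * .Machine$double.eps * az[i]
  }
  w
}

# Univariate-response PLS (NIPALS). X, y assumed centered/scaled.
# Returns the regression coefficient vector on that scale and the number of
# components actually extracted (less than ncomp when rank runs out).
pls1_fit <- function(X, y, ncomp) {
  p <- ncol(X)
  E <- X
  f <- y
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  tol <- .Machine$double.eps^0.5 * max(1, sqrt(sum(y^2)))
  a <- 0L
  for (j in seq_len(ncomp)) {
    zv <- crossprod(E, f)
    nz <- sqrt(sum(zv^2))
    if (!is.finite(nz) || nz < tol) break
    w <- zv / nz
    tvec <- E %*% w
    tt <- sum(tvec^2)
    if (tt < tol^2) break
    W[, j] <- w
    P[, j] <- crossprod(E, tvec) / tt
    Q[j] <- sum(tvec * f) / tt
    E <- E - tvec %*% t(P[, j])
    f <- f - Q[j] * tvec
    a <- j
  }
  if (a == 0L) {
    return(list(beta = numeric(p), ncomp = 0L))
  }
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  beta <- Wa %*% solve(crossprod(Pa, Wa), Q[seq_len(a)])
  list(beta = drop(beta), ncomp = a)
}

# Core SPLS loop on standardized data. At each step k the covariance of the
# predictors with the current residual is thresholded, the active set grows
# by the surviving indices (plus any force-in columns), and the outcome is
# refit by PLS on the active columns with min(k, |active|) components. The
# state after step k does not depend on the total number of steps, so when
# `record = TRUE` the coefficient vector after every step is kept: column k
# is exactly the fit one would get by running the algorithm with K = k.
spls_steps <- function(Xs, ys, K, eta, force_in = integer(), record = FALSE) {
  p <- ncol(Xs)
  beta <- numeric(p)
  active <- sort(unique(as.integer(force_in)))
  directions <- matrix(0, p, K)
  betas <- if (record) matrix(0, p, K) else NULL
  rank_warn <- FALSE
  for (k in seq_len(K)) {
    r <- ys - drop(Xs %*% beta)
    z <- drop(crossprod(Xs, r))
    w <- soft_threshold_direction(z, eta)
    directions[, k] <- w
    active <- sort(unique(c(active, which(w != 0))))
    ncomp <- min(k, length(active))
    fit <- pls1_fit(Xs[, active, drop = FALSE], ys, ncomp)
    if (fit$ncomp < ncomp) rank_warn <- TRUE
    beta <- numeric(p)
    beta[active] <- fit$beta
    if (record) betas[, k] <- beta
  }
  list(beta = beta, active = active, directions = directions,
       betas = betas, rank_warn = rank_warn)
}

#' Fit a sparse partial least squares model for one tuning pair
#'
#' Fits a univariate-response sparse PLS regression with `K` latent
#' components and sparsity `eta`. Predictors and outcome are standardized
#' internally; coefficients are reported on the standardized scale, with
#' exact zeros for predictors outside the active set. Force-in predictors
#' of the dataset are added to the active set at every step, so they always
#' carry a coefficient.
#'
#' @param data an [spls_dataset].
#' @param K integer number of latent components, `1 <= K <= min(p, n - 1)`.
#' @param eta sparsity parameter in `[0, 1)`; larger values select fewer
#'   predictors.
#' @return An object of class `spls_fit` with components `beta` (named,
#'   length p, standardized scale), `active_set` (integer indices),
#'   `directions` (p x K matrix of thresholded direction vectors), `K`,
#'   `eta` and `scaler` (standardization constants for X and y).
#' @examples
#' d <- spls_dataset(matrix(rnorm(200), 50, 4), rnorm(50))
#' fit <- fit_spls(d, K = 2, eta = 0.5)
#' coef(fit)
#' @seealso [run_grid()] to fit every `(K, eta)` cell of a grid at once.
#' @export
fit_spls <- function(data, K, eta) {
  stopifnot(inherits(data, "spls_dataset"))
  n <- nrow(data$X)
  p <- ncol(data$X)
  K <- as.integer(K)
  kmax <- min(p, n - 1L)
  if (length(K) != 1L || is.na(K) || K < 1L || K > kmax) {
    stop("`K` must be an integer in 1..min(p, n - 1) = ", kmax)
  }
  if (!is.numeric(eta) || length(eta) != 1L || eta < 0 || eta >= 1) {
    stop("`eta` must be a single value in [0, 1)")
  }
  sx <- standardize_columns(data$X)
  sy <- standardize_columns(data$y)
  st <- spls_steps(sx$values, sy$values, K, eta, data$force_in)
  if (st$rank_warn) {
    warning("active submatrix was rank deficient; effective number of ",
            "components was reduced")
  }
  beta <- st$beta
  names(beta) <- data$names
  structure(list(beta = beta, active_set = st$active,
                 directions = st$directions, K = K, eta = eta,
                 names = data$names, force_in = data$force_in,
                 scaler = list(x_center = sx$center, x_scale = sx$scale,
                               y_center = sy$center, y_scale = sy$scale)),
            class = "spls_fit")
}

#' @export
print.spls_fit <- function(x, ...) {
  cat("Sparse PLS fit: K = ", x$K, ", eta = ", format(x$eta), "\n", sep = "")
  cat("Selected ", length(x$active_set), " of ", length(x$beta),
      " predictors:\n  ", sep = "")
  cat(paste(x$names[x$active_set], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.spls_fit <- function(object, ...) object$beta

#' Predict from a fitted sparse PLS model
#'
#' Applies the training standardization to new predictor rows, multiplies
#' by the standardized coefficient vector, and maps back to the original
#' outcome scale.
#'
#' @param object an [spls_fit].
#' @param newdata numeric matrix (or data frame) with the same predictors,
#'   in the same order, as the training data.
#' @param ... unused.
#' @return numeric vector of predicted outcomes, one per row of `newdata`.
#' @export
predict.spls_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  p <- length(object$beta)
  if (ncol(newdata) != p) {
    stop("`newdata` has ", ncol(newdata), " columns; the model expects ", p)
  }
  sc <- object$scaler
  Xs <- sweep(sweep(newdata, 2L, sc$x_center, "-"), 2L, sc$x_scale, "/")
  drop(sc$y_center + sc$y_scale * (Xs %*% object$beta))
}

#' Write standardized coefficients to a tab-separated file
#'
#' Emits a two-column TSV (`predictor`, `standardized_beta`) with zeros
#' written explicitly for predictors outside the active set.
#'
#' @param fit an [spls_fit].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(fit, path) {
  stopifnot(inherits(fit, "spls_fit"))
  df <- data.frame(predictor = fit$names,
                   standardized_beta = unname(fit$beta))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
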