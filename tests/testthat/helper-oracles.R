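# Independent oracles and small fixture builders used across the suite.

# PLS1 coefficients via the Krylov-subspace characterization: the K-component
# PLS solution is the least-squares fit of y restricted to
# span{s, Gs, ..., G^(K-1) s} with s = X'y, G = X'X. This is a different
# formulation from the NIPALS deflation used by the package.
pls1_krylov <- function(Xs, ys, K) {
  s <- crossprod(Xs, ys)
  G <- crossprod(Xs)
  Kr <- matrix(0, ncol(Xs), K)
  v <- s
  for (j in seq_len(K)) {
    Kr[, j] <- v
    v <- G %*% v
  }
  a <- qr.solve(Xs %*% Kr, ys)
  drop(Kr %*% a)
}

# a small full-rank regression problem
random_dataset <- function(n = 20, p = 5, seed = 1, force_in = integer()) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p)
    y <- drop(X %*% beta) + rnorm(n)
    spls_dataset(X, y, force_in = force_in)
  })
}

# externally studentized residual of row i in a simple regression of y on x,
# recomputed by literally deleting the row and refitting
loo_studentized <- function(x, y, i) {
  fit <- lm(y ~ x)
  h <- lm.influence(fit, do.coef = FALSE)$hat
  e <- resid(fit)
  fit_i <- lm(y[-i] ~ x[-i])
  s_i <- summary(fit_i)$sigma
  unname(e[i] / (s_i * sqrt(1 - h[i])))
}
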