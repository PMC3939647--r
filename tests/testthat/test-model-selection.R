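test_that("leave-one-out tuning is deterministic and equals v = n folds", {
  d <- random_dataset(n = 15, p = 4, seed = 21)
  g1 <- cv_mspe(d, k_grid = 1:3, eta_grid = c(0.2, 0.6), folds = "loo", seed = 1)
  g2 <- cv_mspe(d, k_grid = 1:3, eta_grid = c(0.2, 0.6), folds = "loo", seed = 2)
  expect_identical(g1$mspe, g2$mspe)
  g3 <- cv_mspe(d, k_grid = 1:3, eta_grid = c(0.2, 0.6), folds = 15, seed = 99)
  expect_identical(g1$mspe, g3$mspe)
  expect_true(all(is.finite(g1$mspe)) && all(g1$mspe >= 0))
})

test_that("k-fold tuning depends on the fold-assignment seed", {
  d <- generate_dataset(simulation_spec(n = 40, breakpoints = c(0, 3, 6),
                                        outcome_coefficients = c(1, 0)),
                        seed = 4)
  a <- cv_mspe(d, k_grid = 1:3, eta_grid = c(0.3, 0.6, 0.9), folds = 5, seed = 1)
  b <- cv_mspe(d, k_grid = 1:3, eta_grid = c(0.3, 0.6, 0.9), folds = 5, seed = 2)
  expect_true(any(a$mspe != b$mspe))
  # but the same seed reproduces the grid exactly
  a2 <- cv_mspe(d, k_grid = 1:3, eta_grid = c(0.3, 0.6, 0.9), folds = 5, seed = 1)
  expect_identical(a$mspe, a2$mspe)
})

test_that("K values above the fold-dependent bound are dropped with a warning", {
  d <- random_dataset(n = 10, p = 8, seed = 6)
  # v = 2: bound = min(8, 5) = 5
  expect_warning(g <- cv_mspe(d, k_grid = 1:8, eta_grid = 0.5, folds = 2,
                              seed = 1), "bound")
  expect_identical(g$k_grid, 1:5)
  expect_error(suppressWarnings(
    cv_mspe(d, k_grid = 8, eta_grid = 0.5, folds = 2, seed = 1)),
    "admissible")
})

test_that("select_optimal matches an exhaustive scan and documents its tie-breaks", {
  d <- random_dataset(n = 20, p = 5, seed = 31)
  g <- cv_mspe(d, k_grid = 1:4, eta_grid = seq(0.1, 0.9, 0.2), folds = "loo")
  opt <- select_optimal(g)
  # brute-force scan over every cell
  best <- Inf
  for (i in seq_along(g$k_grid)) for (j in seq_along(g$eta_grid)) {
    if (g$mspe[i, j] < best) best <- g$mspe[i, j]
  }
  expect_equal(opt$mspe, best)
  expect_equal(g$mspe[paste0("K", opt$K), paste0("eta", format(opt$eta))],
               best, ignore_attr = TRUE)

  # ties: smaller K wins, then larger eta
  fake <- g
  fake$mspe[] <- 1
  fake$mspe[2, 1] <- 0.5   # K = 2
  fake$mspe[3, 4] <- 0.5   # K = 3
  tie <- select_optimal(fake)
  expect_equal(tie$K, g$k_grid[2])
  fake$mspe[2, 3] <- 0.5   # same K, larger eta
  expect_equal(select_optimal(fake)$eta, g$eta_grid[3])
  # single-cell grid returns that cell
  one <- cv_mspe(d, k_grid = 2, eta_grid = 0.4, folds = "loo")
  expect_equal(select_optimal(one), list(K = 2L, eta = 0.4,
                                         mspe = one$mspe[1, 1]),
               ignore_attr = TRUE)
})

test_that("seed-sensitivity tallies conserve the number of seeds and reproduce", {
  d <- generate_dataset(simulation_spec(n = 30, breakpoints = c(0, 3, 6),
                                        outcome_coefficients = c(1, 0)),
                        seed = 8)
  rep1 <- seed_sensitivity(d, k_grid = 1:2, eta_grid = c(0.3, 0.7), v = 5,
                           n_seeds = 12, base_seed = 99)
  expect_equal(sum(rep1$counts$count), 12)
  one <- seed_sensitivity(d, k_grid = 1:2, eta_grid = c(0.3, 0.7), v = 5,
                          n_seeds = 1, base_seed = 5)
  expect_equal(nrow(one$counts), 1L)
  expect_equal(one$counts$count, 1L)
  rep2 <- seed_sensitivity(d, k_grid = 1:2, eta_grid = c(0.3, 0.7), v = 5,
                           n_seeds = 12, base_seed = 99)
  expect_identical(rep1$counts, rep2$counts)
  expect_error(seed_sensitivity(d, v = 30), "less than n")
})
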