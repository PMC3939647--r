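test_that("left-skew transform evaluates and stays strictly monotone", {
  expect_equal(transform_left_skew(100), 0)
  expect_equal(transform_left_skew(94), -log(7))
  expect_equal(transform_left_skew(0), -log(101))
  expect_error(transform_left_skew(101), "less than 101")
  grid <- seq(0, 100, by = 0.25)
  expect_true(all(diff(transform_left_skew(grid)) > 0))
})

test_that("influential filter matches leave-one-out studentized residuals", {
  # a clean line plus one gross outlier in y
  withr::with_seed(17, {
    x <- rnorm(20)
    y <- 2 * x + rnorm(20, sd = 0.3)
  })
  y[7] <- y[7] + 6
  d <- spls_dataset(cbind(x = x), y)
  out <- influential_filter(d, threshold = 2.5)
  expect_true(7 %in% out$report$removed_rows)
  expect_equal(out$report$rows_remaining, nrow(out$data$X))
  # the recorded residual equals a literal delete-row-and-refit recomputation
  rec <- out$report$records
  r7 <- rec$residual[rec$row == 7][1]
  expect_equal(r7, loo_studentized(x, y, 7), tolerance = 1e-10)
})

test_that("filter removes nothing for exact or clean fits and is idempotent", {
  x <- seq_len(12)
  d_exact <- spls_dataset(cbind(x = as.numeric(x)), 3 * x - 1)
  out <- influential_filter(d_exact)
  expect_length(out$report$removed_rows, 0)

  d <- random_dataset(n = 30, p = 3, seed = 71)
  none <- influential_filter(d, threshold = Inf)
  expect_length(none$report$removed_rows, 0)
  once <- influential_filter(d, threshold = 4)
  twice <- influential_filter(once$data, threshold = 4)
  expect_length(twice$report$removed_rows, 0)
})

test_that("constant predictors are skipped with a warning, not fatal", {
  X <- cbind(a = rnorm(10), b = rep(1, 10))
  d <- list(X = X, y = rnorm(10), names = c("a", "b"), force_in = integer())
  class(d) <- "spls_dataset"
  expect_warning(out <- influential_filter(d, threshold = 2.5), "constant")
  expect_s3_class(out$data, "spls_dataset")
})

test_that("condition number agrees with an independent SVD and flags singularity", {
  expect_equal(condition_number(diag(5) * 3, add_intercept = FALSE)$value, 1)
  withr::with_seed(19, X <- matrix(rnorm(250), 50, 5))
  got <- condition_number(X, add_intercept = TRUE)
  # oracle: base kappa(exact) on the manually equilibrated design
  D <- cbind(1, X)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  expect_equal(got$value, kappa(D, exact = TRUE), tolerance = 1e-10)
  expect_false(condition_number(X)$exceeds_limit)

  dup <- cbind(X, X[, 1])
  flag <- condition_number(dup)
  expect_identical(flag$value, Inf)
  expect_true(flag$exceeds_limit)
})

test_that("condition number is invariant to column permutation and rescaling", {
  withr::with_seed(23, X <- matrix(rnorm(200), 40, 5))
  v0 <- condition_number(X)$value
  expect_equal(condition_number(X[, c(3, 1, 5, 2, 4)])$value, v0,
               tolerance = 1e-10)
  X2 <- sweep(X, 2, c(10, 0.01, 3, 7, 100), "*")
  expect_equal(condition_number(X2)$value, v0, tolerance = 1e-8)
})

test_that("CSV reading applies transforms, drops incomplete rows, round-trips", {
  df <- data.frame(hippocampus = c(9.1, 8.4, 10.2, 9.7),
                   pallidum = c(240, 260, 255, 251),
                   score = c(90, 94, 88, 97))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)

  d <- read_dataset(path, outcome_name = "score")
  expect_identical(d$names, c("hippocampus", "pallidum"))
  expect_equal(d$y, df$score)

  # round trip preserves values to full precision
  out <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, out, outcome_name = "score")
  d2 <- read_dataset(out, outcome_name = "score")
  expect_equal(d2$X, d$X)
  expect_equal(d2$y, d$y)

  cfg <- preprocess_config(outcome_transform = "left_skew_3ms",
                           log_columns = "pallidum")
  dt <- read_dataset(path, "score", force_in_names = "hippocampus",
                     config = cfg)
  expect_equal(dt$y, -log(101 - df$score))
  expect_equal(unname(dt$X[, "pallidum"]), log(df$pallidum))
  expect_identical(dt$force_in, 1L)

  df$hippocampus[2] <- NA
  write.csv(df, path, row.names = FALSE)
  expect_message(d3 <- read_dataset(path, "score"), "1 row")
  expect_equal(nrow(d3$X), 3L)

  expect_error(read_dataset(path, "nope"), "not found")
  expect_error(read_dataset(path, "score", force_in_names = "ghost"),
               "unknown column")
})

test_that("non-numeric cells are located in the error message", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "oops,4", "5,6"), path)
  expect_error(read_dataset(path, "b"), "column 'a', row 2")
})
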