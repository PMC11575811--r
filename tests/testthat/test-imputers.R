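test_that("moving mean reproduces the hand-worked window cases", {
  # single missing day, run length 1: window of days [i-1, i+1] -> mean(2, 4)
  s <- toy_series(c(1, 2, NA, 4, 5))
  expect_equal(impute_moving_mean(s)$values, c(1, 2, 3, 4, 5))
  # leading run of 2: window [i-2, i+2] truncated at the edge, all observed
  # neighbours equal 6
  s2 <- toy_series(c(NA, NA, 6, 6, 6, 6))
  expect_equal(impute_moving_mean(s2)$values, rep(6, 6))
  # no missing values: identity
  s3 <- toy_series(c(3, 1, 4))
  expect_identical(impute_moving_mean(s3)$values, s3$values)
  expect_error(impute_moving_mean(toy_series(c(NA, NA))), "fully missing")
})

test_that("moving mean widens the window until it finds observed data", {
  # run of 1 at position 2, but the 2L+1 window [1,3] is all missing:
  # doubling reaches day 5
  s <- toy_series(c(NA, NA, NA, NA, 8, 8))
  out <- impute_moving_mean(s)
  expect_equal(out$values, rep(8, 6))
})

test_that("moving mean never modifies observed values and stays in range", {
  set.seed(21)
  for (rep in 1:1000) {
    n <- sample(20:60, 1)
    v <- rlnorm(n, 1, 1)
    k <- sample(1:floor(n / 3), 1)
    idx <- sample(n, k)
    g <- replace(v, idx, NA)
    if (all(is.na(g))) next
    out <- impute_moving_mean(toy_series(g))$values
    expect_identical(out[-idx], v[-idx])
    expect_false(anyNA(out))
    # each imputed value is a mean of observed values, so it lies within
    # the observed range
    expect_true(all(out[idx] >= min(v[-idx]) - 1e-12 &
                      out[idx] <= max(v[-idx]) + 1e-12))
  }
})

test_that("initial fill handles mean, linear, and edge cases", {
  expect_equal(initial_fill(c(1, NA, 3), "linear"), c(1, 2, 3))
  expect_equal(initial_fill(c(1, NA, 3), "mean"), c(1, 2, 3))
  expect_equal(initial_fill(c(NA, 5, 5), "linear"), c(5, 5, 5))  # flat edge
  expect_equal(initial_fill(c(2, NA, NA, 8), "linear"), c(2, 4, 6, 8))
  expect_equal(initial_fill(c(2, NA, NA, 8), "mean"), c(2, 5, 5, 8))
  expect_error(initial_fill(c(NA, NA), "mean"), "fully missing")
})

test_that("assemble_matrix stacks historical and replicate columns", {
  hist <- replicate(5, runif(12), simplify = FALSE)
  reps <- replicate(100, replace(runif(12), sample(12, 3), NA), simplify = FALSE)
  gm <- assemble_matrix(hist[1:4], reps, reference = hist[[5]],
                        include_reference_year = TRUE)
  expect_equal(ncol(gm$values), 105L)
  expect_equal(dim(gm$mask), dim(gm$values))
  expect_identical(gm$mask, is.na(gm$values))
  # mask true exactly at replicate gaps (historical columns complete here)
  expect_equal(sum(gm$mask[, 1:5]), 0L)
  expect_equal(sum(gm$mask), 300L)

  no_ref <- assemble_matrix(hist[1:4], reps, reference = hist[[5]],
                            include_reference_year = FALSE)
  expect_equal(ncol(no_ref$values), 104L)
  only_hist <- assemble_matrix(hist, list())
  expect_equal(ncol(only_hist$values), 5L)
  expect_error(assemble_matrix(hist, list(runif(5))), "same length")
})

test_that("gappy_svd recovers an exact rank-1 matrix through 10% gaps", {
  x <- rank1_matrix(20, 8)
  set.seed(1)
  masked <- sample(length(x), round(0.1 * length(x)))
  xg <- replace(x, masked, NA)
  fit <- gappy_svd(xg, n_modes = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$completed - x)), 1e-3)
  # observed entries untouched, bit for bit
  expect_identical(fit$completed[-masked], x[-masked])
})

test_that("gappy_svd is exact on constant matrices and no-ops on full data", {
  x <- matrix(3.5, 12, 6)
  xg <- replace(x, c(2, 15, 40), NA)
  fit <- gappy_svd(xg, n_modes = 1)
  expect_true(all(abs(fit$completed - 3.5) < 1e-3))

  full <- matrix(runif(24), 6, 4)
  fit0 <- gappy_svd(full, n_modes = 2)
  expect_identical(fit0$completed, full)
  expect_equal(fit0$final_delta, 0)
  expect_true(fit0$converged)
})

test_that("gappy_svd recovers exact low-rank structure across seeds", {
  for (seed in 1:10) {
    set.seed(seed)
    r <- sample(1:3, 1)
    u <- matrix(rlnorm(30 * r), 30, r)
    w <- matrix(rlnorm(10 * r), 10, r)
    x <- u %*% t(w)
    masked <- sample(length(x), round(0.08 * length(x)))
    xg <- replace(x, masked, NA)
    fit <- gappy_svd(xg, n_modes = r, init = "mean", tol = 1e-12,
                     max_iter = 5000)
    expect_identical(fit$completed[-masked], x[-masked])
    expect_lt(max(abs(fit$completed - x)) / max(x), 1e-2)
  }
})

test_that("convergence flag is honest and non-convergence is not an error", {
  set.seed(2)
  x <- matrix(rlnorm(200, 2, 1), 20, 10)
  xg <- replace(x, sample(200, 40), NA)
  starved <- gappy_svd(xg, n_modes = 3, max_iter = 1L)
  expect_false(starved$converged)
  expect_gte(starved$final_delta, starved$tol)
  ok <- gappy_svd(xg, n_modes = 3, max_iter = 2000)
  if (ok$converged) expect_lt(ok$final_delta, ok$tol)
})

test_that("relative-delta convergence makes imputation scale-equivariant", {
  x <- rank1_matrix(15, 6) + 0.05
  set.seed(7)
  masked <- sample(length(x), 9)
  xg <- replace(x, masked, NA)
  f1 <- gappy_svd(xg, n_modes = 2, delta = "relative", tol = 1e-10)
  f2 <- gappy_svd(xg * 1e4, n_modes = 2, delta = "relative", tol = 1e-10)
  expect_equal(f2$completed[masked] / 1e4, f1$completed[masked],
               tolerance = 1e-6)
})

test_that("gappy_svd validates its configuration", {
  x <- matrix(runif(20), 5, 4)
  expect_error(gappy_svd(x, n_modes = 5), "n_modes")
  expect_error(gappy_svd(x, n_modes = 0), "n_modes")
  expect_error(gappy_svd(x, n_modes = 1, tol = 0), "tol")
  x[, 2] <- NA
  expect_error(gappy_svd(x, n_modes = 1), "fully masked")
})

test_that("imputed concentrations are clipped at zero", {
  # steep descending structure can push a low-rank extrapolation negative;
  # the clip guarantees physical (nonnegative) concentrations
  set.seed(3)
  x <- outer(c(20, 10, 4, 1, 0.1, 0.01), c(1, 0.5, 0.2, 2, 1.4)) +
    matrix(rnorm(30, 0, 0.2), 6, 5)
  x <- pmax(x, 0)
  xg <- replace(x, c(5, 11, 23), NA)
  fit <- gappy_svd(xg, n_modes = 2)
  expect_true(all(fit$completed >= 0))
})

test_that("gsvd methods expose the fit coherently", {
  x <- rank1_matrix(12, 5)
  set.seed(5)
  masked <- sample(60, 6)
  fit <- gappy_svd(replace(x, masked, NA), n_modes = 1)
  expect_output(print(fit), "Gappy-SVD")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.gsvd")
  expect_gt(sm$energy, 0.99)
  expect_equal(dim(fitted(fit)), dim(x))
  res <- residuals(fit)
  expect_true(all(is.na(res[masked])))
  expect_lt(max(abs(res), na.rm = TRUE), 1e-2)  # near-rank-1 input
})
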