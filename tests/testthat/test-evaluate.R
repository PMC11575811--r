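test_that("rmse matches hand arithmetic and basic identities", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  # differences (3, 4) over N = 2: sqrt(25 / 2)
  expect_equal(rmse(c(4, 7), c(1, 3)), sqrt(25 / 2))
  expect_error(rmse(1:3, 1:4), "same length")
  expect_error(rmse(c(1, NA), c(1, 2)), "missing")
  # homogeneity
  set.seed(8)
  a <- runif(30); b <- runif(30)
  expect_equal(rmse(3 * a, 3 * b), 3 * rmse(a, b))
  # gap-only variant averages over masked days only
  m <- c(TRUE, FALSE)
  expect_equal(rmse(c(4, 7), c(1, 3), mask = m, gap_only = TRUE), 3)
})

test_that("rmse satisfies the triangle-style bound", {
  set.seed(9)
  for (i in 1:50) {
    a <- rnorm(20); b <- rnorm(20); c <- rnorm(20)
    expect_lte(rmse(a, c), rmse(a, b) + rmse(b, c) + 1e-12)
  }
})

make_records <- function(rmse_fun, methods = c("movingmean", "gsvd_mean_5m"),
                         props = c(5, 10, 25), lens = c(3, 5), reps = 10) {
  g <- expand.grid(pollen = "A", station = "S", method = methods,
                   na_prop = props, gap_len = lens, replicate = seq_len(reps),
                   stringsAsFactors = FALSE)
  g$rmse <- rmse_fun(g)
  g
}

test_that("summarize_rmse returns per-cell medians", {
  rec <- make_records(function(g) ave(seq_len(nrow(g)), g$method, g$na_prop,
                                      g$gap_len, FUN = seq_along))
  out <- summarize_rmse(rec)
  expect_equal(nrow(out), 2 * 3 * 2)
  expect_true(all(out$n == 10))
  expect_true(all(out$median_rmse == 5.5))  # median of 1..10

  const <- make_records(function(g) rep(4.2, nrow(g)))
  expect_true(all(summarize_rmse(const)$median_rmse == 4.2))

  one <- rec[rec$method == "movingmean", ]
  expect_setequal(unique(summarize_rmse(one)$method), "movingmean")
})

test_that("a constant-RMSE stratum yields null effects", {
  rec <- make_records(function(g) rep(2, nrow(g)),
                      methods = c("movingmean", "gsvd_mean_5m", "gsvd_interp_10m"))
  fit <- suppressWarnings(fit_error_model(rec))  # zero-residual fit
  expect_true(all(abs(fit$effects$exp_beta - 1) < 1e-10))
})

test_that("reference rows are flagged with exp_beta one", {
  rec <- make_records(function(g) rlnorm(nrow(g)),
                      methods = c("movingmean", "gsvd_mean_5m", "gsvd_interp_10m"),
                      lens = c(3, 5, 7, 10))
  fit <- fit_error_model(rec)
  refs <- fit$effects[fit$effects$reference, ]
  expect_setequal(refs$level, c("movingmean", "5", "3"))
  expect_true(all(refs$exp_beta == 1))
  expect_true(all(fit$effects$ci_low <= fit$effects$exp_beta + 1e-12 &
                    fit$effects$exp_beta <= fit$effects$ci_high + 1e-12))
  expect_true(all(fit$effects$exp_beta > 0))
  expect_output(print(fit), "Ref\\.")
})

test_that("a known multiplicative effect is recovered within its CI", {
  set.seed(10)
  rec <- make_records(function(g) {
    exp(log(3) + log(2) * (g$na_prop == 25) + rnorm(nrow(g), 0, 0.05))
  }, reps = 50)
  fit <- fit_error_model(rec)
  row <- fit$effects[fit$effects$term == "na_prop" & fit$effects$level == "25", ]
  expect_equal(row$exp_beta, 2, tolerance = 0.05)
  expect_true(row$ci_low <= 2 && 2 <= row$ci_high)
})

test_that("exp(beta) equals the ratio of geometric means in the balanced two-group case", {
  set.seed(12)
  rec <- make_records(function(g) rlnorm(nrow(g), meanlog = 0.3 * (g$method != "movingmean")),
                      methods = c("movingmean", "gsvd_mean_5m"),
                      props = 5, lens = 3, reps = 200)
  fit <- fit_error_model(rec)
  gm <- tapply(rec$rmse, rec$method, function(z) exp(mean(log(z))))
  expect_equal(fit$effects$exp_beta[fit$effects$level == "gsvd_mean_5m"],
               unname(gm["gsvd_mean_5m"] / gm["movingmean"]), tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  rec <- make_records(function(g) rep(1, nrow(g)))
  rec$rmse[1] <- 0
  expect_error(fit_error_model(rec), "positive")
  rec2 <- make_records(function(g) rlnorm(nrow(g)))
  expect_error(fit_error_model(rec2, ref_method = "nope"), "not present")
})
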