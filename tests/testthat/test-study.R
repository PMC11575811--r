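# a deliberately small study configuration used across the tests
small_study <- function(seed = 1, reps = 3, master_seed = seed * 17, ...) {
  ds <- make_study_fixture(seed = seed)
  study_config(ds, reps = reps, master_seed = master_seed, ...)
}

test_that("grid arithmetic matches the published design", {
  cfg <- small_study(reps = 2)
  res <- run_study(cfg)
  cells <- unique(res$records[c("pollen", "station", "na_prop", "gap_len")])
  expect_equal(nrow(cells), 48L)  # 12 scenarios x 2 stations x 2 taxa
  # one record per (unit, cell, method, replicate)
  expect_equal(nrow(res$records), 48L * 2L * 3L)
  key <- do.call(paste, res$records[c("pollen", "station", "method",
                                      "na_prop", "gap_len", "replicate")])
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(res$records$rmse >= 0))
  expect_setequal(unique(res$records$method),
                  c("movingmean", "gsvd_mean_5m", "gsvd_interp_10m"))
})

test_that("a single-unit, single-replicate study yields 12 masked series", {
  ds <- make_study_fixture(seed = 3)[1]
  cfg <- study_config(ds, reps = 1,
                      methods = list(movingmean = list(type = "movingmean")),
                      master_seed = 2)
  res <- run_study(cfg)
  expect_equal(nrow(res$records), 12L)
  expect_equal(nrow(res$scenarios), 12L)
})

test_that("the study is deterministic: identical seeds give identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_study(small_study(reps = 2), out_dir = d1)
  run_study(small_study(reps = 2), out_dir = d2)
  for (f in c("records.csv", "scenarios.csv", "medians.csv", "effects.csv",
              "season_stats.csv", "convergence.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different master seed changes the records
  d3 <- withr::local_tempdir()
  run_study(small_study(reps = 2, master_seed = 999), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "records.csv")),
                         readLines(file.path(d3, "records.csv"))))
})

test_that("output files carry the tidy result schema", {
  d <- withr::local_tempdir()
  res <- run_study(small_study(reps = 2), out_dir = d)
  rec <- read.csv(file.path(d, "records.csv"))
  expect_named(rec, c("pollen", "station", "method", "na_prop", "gap_len",
                      "replicate", "rmse"))
  med <- read.csv(file.path(d, "medians.csv"))
  expect_named(med, c("pollen", "station", "method", "na_prop", "gap_len",
                      "n", "median_rmse"))
  eff <- read.csv(file.path(d, "effects.csv"))
  expect_named(eff, c("stratum", "term", "level", "exp_beta", "ci_low",
                      "ci_high", "reference"))
  ss <- read.csv(file.path(d, "season_stats.csv"))
  expect_true(all(c("pollen", "station", "mean", "sd", "cv", "vin",
                    "duration") %in% names(ss)))
  scn <- read.csv(file.path(d, "scenarios.csv"))
  expect_named(scn, c("pollen", "station", "season_len", "na_prop", "gap_len",
                      "n_gaps", "total_na_days", "resulting_pct", "replicate",
                      "seed"))
})

test_that("an incomplete target year aborts before simulating", {
  ds <- make_study_fixture(seed = 4)
  ds[[1]]$values[which(format(ds[[1]]$dates, "%Y-%m-%d") == "2022-03-01")] <- NA
  cfg <- study_config(ds, reps = 1)
  expect_error(run_study(cfg), "incomplete")
})

test_that("pooled scope with the reference year reconstructs the withheld truth", {
  # the pooled design leaks the complete target year through the column
  # consensus: its apparent error collapses far below the honest
  # per-replicate error of the same scenario
  ds <- make_study_fixture(seed = 5)[1]
  gsvd_only <- list(gsvd_mean_5m = list(type = "gsvd", n_modes = 5L,
                                        init = "mean"))
  base <- study_config(ds, props = 0.05, lens = 3L, reps = 20,
                       methods = gsvd_only, master_seed = 6)
  pooled <- study_config(ds, props = 0.05, lens = 3L, reps = 20,
                         methods = gsvd_only, master_seed = 6,
                         gsvd_scope = "pooled", include_reference_year = TRUE)
  r_base <- run_study(base)$records$rmse
  r_pooled <- run_study(pooled)$records$rmse
  expect_lt(median(r_pooled), 0.01 * median(r_base))
})
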