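# Information criteria, fit records, model comparison, pipeline caching.

test_that("aic and bic follow their definitions", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-100, 6), 212)
  expect_equal(bic(-100, 6, exp(2)), 212)
  expect_error(bic(-10, 2, 0))
})

test_that("fit_result enforces the criterion invariants", {
  f <- fit_result("m", list(), loglik = -50, n_params = 4, n_obs = 120)
  expect_equal(f$aic, 2 * 4 - 2 * (-50))
  expect_equal(f$bic, 4 * log(120) - 2 * (-50))
  expect_error(fit_result("m", list(), loglik = NaN, n_params = 1, n_obs = 10))
})

test_that("comparison handles single models, nesting ties, and missing fits", {
  f1 <- fit_result("a", list(), -50, 4, 100)
  single <- compare_fits(list(list(a = f1), list(a = f1)))
  expect_equal(single$table$mean_delta_aic, 0)
  expect_equal(single$table$n_best_aic, 2)
  # nested pair reaching identical loglik: fewer parameters wins both
  full <- fit_result("full", list(), -80, 6, 200)
  part <- fit_result("part", list(), -80, 5, 200)
  cmp <- compare_fits(list(list(full = full, part = part)))
  expect_equal(cmp$table$n_best_aic[cmp$table$model == "part"], 1)
  expect_equal(cmp$table$n_best_bic[cmp$table$model == "part"], 1)
  expect_equal(cmp$table$mean_delta_aic[cmp$table$model == "full"], 2)
  expect_true(all(cmp$per_dataset$delta_aic >= 0))
  expect_error(compare_fits(list(list(full = full, part = part),
                                 list(full = full))),
               "missing")
})

test_that("YAML configs override pipeline defaults field-wise", {
  skip_if_not_installed("yaml")
  path <- system.file("extdata", "demo_config.yaml", package = "swapkit")
  cfg <- swapkit:::read_pipeline_config(path)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$n_trials_per_level, 60)
  expect_equal(cfg$generator$conjunction,
               c(low = 0.35, medium = 0.55, high = 0.8))
  expect_equal(cfg$fit$grid_size, 720)        # default preserved under merge
})

test_that("pipeline runs, caches, and recomputes downstream stages", {
  cfg <- pipeline_config(n_trials_per_level = 30L, seed = 3L)
  cfg$fit$models <- "im_partial"
  cfg$fit$im_maxit <- 60L; cfg$fit$im_restarts <- 1L
  cfg$predictor$n_iter <- 40L
  dir1 <- tempfile("pipe")
  r1 <- suppressMessages(run_pipeline(cfg, dir1))
  expect_true(file.exists(file.path(dir1, "swap_estimates.tsv")))
  # identical seed and config in a fresh directory: identical tables
  dir2 <- tempfile("pipe")
  r2 <- suppressMessages(run_pipeline(cfg, dir2))
  expect_identical(readLines(file.path(dir1, "responses_location_report.tsv")),
                   readLines(file.path(dir2, "responses_location_report.tsv")))
  expect_equal(r1$estimates, r2$estimates)
  expect_equal(r1$predictions, r2$predictions)
  # deleting one intermediate only recomputes from that stage
  before <- readLines(file.path(dir1, "swap_predictions.tsv"))
  sim_mtime <- file.mtime(file.path(dir1, "responses_location_report.tsv"))
  unlink(file.path(dir1, "swap_predictions.tsv"))
  r3 <- suppressMessages(run_pipeline(cfg, dir1))
  expect_identical(readLines(file.path(dir1, "swap_predictions.tsv"))[-1],
                   before[-1])   # first line carries a timestamp comment
  expect_identical(file.mtime(file.path(dir1, "responses_location_report.tsv")),
                   sim_mtime)
  unlink(c(dir1, dir2), recursive = TRUE)
})
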