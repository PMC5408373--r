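test_that("relative bias, MSE and pct_biased follow their definitions", {
  expect_equal(relative_bias(c(-0.04, -0.04), -0.04), 0)
  expect_equal(relative_bias(c(-0.02), -0.04), 50)
  expect_error(relative_bias(1, 0), "att_true = 0")
  expect_equal(mse(c(-0.04, -0.04), -0.04), 0)
  expect_equal(mse(c(-0.03, -0.05), -0.04), 1e-4)
  # deviation of -0.08 from -0.04 is exactly 100%, not > 100%
  expect_equal(unname(pct_biased(c(-0.08, -0.04), -0.04)),
               c(50, 50, 50, 0))
  expect_equal(unname(pct_biased(c(-0.04, -0.04), -0.04)), rep(0, 4))
})

test_that("MSE decomposes into variance plus squared bias", {
  set.seed(601)
  for (i in 1:5) {
    e <- rnorm(50, -0.04, 0.01)
    n <- length(e)
    decomp <- var(e) * (n - 1) / n + (mean(e) - (-0.04))^2
    expect_equal(mse(e, -0.04), decomp, tolerance = 1e-12)
  }
})

test_that("pct_biased percentages are non-increasing in the margin", {
  set.seed(602)
  for (i in 1:5) {
    e <- rnorm(100, -0.04, 0.03)
    p <- pct_biased(e, -0.04)
    expect_true(all(diff(p) <= 0))
  }
})

test_that("a replicate is deterministic and collapses above the largest SMD", {
  spec <- calibrated_A()
  r1 <- run_replicate(spec, default_model(), n_units = 2000, seed = 603)
  r2 <- run_replicate(spec, default_model(), n_units = 2000, seed = 603)
  expect_identical(r1, r2)
  expect_length(r1$estimates, 26L)
  # thresholds above every SMD adjust nothing: DR equals crude
  big <- run_replicate(spec, default_model(), n_units = 2000,
                       thresholds = c(0.9, 0.95), seed = 603)
  expect_equal(unname(big$estimates[-1]),
               rep(unname(big$estimates["crude"]), 2))
})

test_that("DR estimates are piecewise constant in the threshold", {
  spec <- calibrated_A()
  set.seed(604)
  co <- generate_cohort(2000, spec, default_model())
  ps <- fit_propensity(co)
  mt <- nearest_neighbor_match(ps$ps_hat, co$Z)
  tab <- balance_table(co, mt)
  grid <- smd_thresholds()
  ests <- vapply(grid, function(t)
    double_robust_att(mt, co, select_unbalanced(tab, t))$risk_difference,
    numeric(1))
  # brute-force re-selection: the estimate changes only at thresholds where
  # some covariate's SMD enters the step (i.e. the selected set changes)
  for (k in seq_len(24)) {
    same_set <- setequal(select_unbalanced(tab, grid[k]),
                         select_unbalanced(tab, grid[k + 1]))
    if (same_set) {
      expect_identical(ests[k], ests[k + 1])
    } else {
      expect_false(identical(ests[k], ests[k + 1]))
    }
  }
})

test_that("run_study aggregates, orders percentiles and writes outputs", {
  out <- withr::local_tempdir()
  cfg <- study_config(n_units = 1500, n_replicates = 4, scenarios = "A",
                      thresholds = c(0.05, 0.10, 0.20), seed = 605,
                      n_true = 2e4, n_cal = 2e4, out_dir = out)
  res <- run_study(cfg, default_model(), progress = FALSE)
  expect_s3_class(res, "study_result")
  expect_equal(nrow(res$summary), 4L)   # crude + 3 thresholds
  expect_true(all(res$summary$p2.5 <= res$summary$mean))
  expect_true(all(res$summary$mean <= res$summary$p97.5))
  expect_true(all(res$summary$mse >=
                    (res$summary$mean - res$summary$att_true)^2 - 1e-12))
  pb <- as.matrix(res$summary[, c("gt25", "gt50", "gt75", "gt100")])
  expect_true(all(t(apply(pb, 1, diff)) <= 0))
  expect_true(file.exists(file.path(out, "replicates.csv")))
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "balance.csv")))
  expect_true(file.exists(file.path(out, "run_log.txt")))
  # full-study determinism under the master seed
  cfg2 <- study_config(n_units = 1500, n_replicates = 4, scenarios = "A",
                       thresholds = c(0.05, 0.10, 0.20), seed = 605,
                       n_true = 2e4, n_cal = 2e4)
  res2 <- run_study(cfg2, default_model(), progress = FALSE)
  expect_equal(res2$summary, res$summary)
  expect_equal(res2$att_true, res$att_true)
})

test_that("study plots build without error", {
  cfg <- study_config(n_units = 1500, n_replicates = 3, scenarios = "A",
                      thresholds = c(0.05, 0.10), seed = 606,
                      n_true = 2e4, n_cal = 2e4)
  res <- run_study(cfg, default_model(), progress = FALSE)
  expect_s3_class(plot_estimates(res), "ggplot")
  expect_s3_class(plot_relative_bias(res), "ggplot")
  expect_s3_class(plot_mse(res), "ggplot")
  expect_s3_class(plot_balance(res), "ggplot")
})
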