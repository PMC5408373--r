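make_matched <- function(treated, control) {
  structure(list(pairs = data.frame(treated = treated, control = control),
                 J = length(treated)),
            class = "matched_sample")
}

test_that("crude estimator enumerates pair differences", {
  mt <- make_matched(1:2, 3:4)
  expect_equal(crude_att(mt, c(0, 0, 0, 0))$risk_difference, 0)
  expect_equal(crude_att(mt, c(1, 0, 0, 0))$risk_difference, 0.5)
  # permutation invariance of the pair order
  mt2 <- make_matched(2:1, 4:3)
  y <- c(1, 0, 1, 0)
  expect_equal(crude_att(mt, y)$risk_difference,
               crude_att(mt2, y)$risk_difference)
})

test_that("double-robust with an empty adjustment set collapses to crude", {
  s <- small_matched()
  dr <- double_robust_att(s$matched, s$cohort, character(0))
  cr <- crude_att(s$matched, s$cohort$Y)
  expect_identical(dr$risk_difference, cr$risk_difference)
})

test_that("adjustment is inert when the outcome ignores the covariates", {
  m <- default_model()
  alpha0 <- default_alpha(); alpha0[] <- 0
  spec <- calibrate_scenario(scenario_spec("A", alpha = alpha0),
                             m, n_cal = 2e4, seed = 501)
  co <- generate_cohort(10000, spec, m, seed = 502)
  ps <- fit_propensity(co)
  mt <- nearest_neighbor_match(ps$ps_hat, co$Z, seed = 503)
  dr <- double_robust_att(mt, co, paste0("W", 1:15))
  cr <- crude_att(mt, co$Y)
  # adjusting outcome-irrelevant covariates moves the estimate only by noise
  se <- sqrt(2 * 0.08 * 0.92 / mt$J)
  expect_lt(abs(dr$risk_difference - cr$risk_difference), se)
})

test_that("double-robust estimate matches a brute-force MLE oracle", {
  # 6 pairs, one binary adjusted covariate; oracle fits each within-arm
  # logistic by direct likelihood maximization and predicts by hand
  co <- generate_cohort(200, calibrated_A(), default_model(), seed = 504)
  ti <- 1:6; ci <- 7:12
  co$Y[ti] <- c(1, 0, 1, 0, 0, 1)
  co$W[ti, "W1"] <- c(1, 1, 0, 0, 1, 0)
  co$Y[ci] <- c(1, 1, 0, 0, 1, 0)
  co$W[ci, "W1"] <- c(1, 0, 1, 0, 0, 1)
  mt <- make_matched(ti, ci)

  brute_fit <- function(y, x) {
    nll <- function(b) -sum(y * (b[1] + b[2] * x) -
                              log(1 + exp(b[1] + b[2] * x)))
    optim(c(0, 0), nll, method = "BFGS",
          control = list(reltol = 1e-14, maxit = 1000))$par
  }
  b1 <- brute_fit(co$Y[ti], co$W[ti, "W1"])
  b0 <- brute_fit(co$Y[ci], co$W[ci, "W1"])
  xt <- co$W[ti, "W1"]
  oracle <- mean(plogis(b1[1] + b1[2] * xt)) -
    mean(plogis(b0[1] + b0[2] * xt))

  dr <- double_robust_att(mt, co, "W1")
  expect_equal(dr$risk_difference, oracle, tolerance = 1e-6)
  # treated-side mean prediction equals the treated arm's observed rate
  expect_equal(dr$p1_bar, mean(co$Y[ti]), tolerance = 1e-8)
})

test_that("within-arm separation falls back to a finite penalized fit", {
  co <- generate_cohort(400, calibrated_A(), default_model(), seed = 505)
  ti <- 1:50; ci <- 51:100
  # W2 perfectly separates the outcome in the treated arm
  co$W[ti, "W2"] <- rep(c(1, 0), 25)
  co$Y[ti] <- co$W[ti, "W2"]
  co$Y[ci] <- rbinom(50, 1, 0.2 + 0.3 * co$W[ci, "W2"])
  if (length(unique(co$Y[ci])) == 1) co$Y[ci[1]] <- 1 - co$Y[ci[1]]
  mt <- make_matched(ti, ci)
  dr <- double_robust_att(mt, co, "W2")
  expect_gte(dr$fallbacks, 1L)
  expect_true(is.finite(dr$risk_difference))
  expect_true(dr$risk_difference >= -1 && dr$risk_difference <= 1)
})

test_that("a constant-outcome arm predicts its observed proportion", {
  co <- generate_cohort(100, calibrated_A(), default_model(), seed = 506)
  ti <- 1:10; ci <- 11:20
  co$Y[ti] <- 0
  co$Y[ci] <- c(1, rep(0, 9))
  mt <- make_matched(ti, ci)
  dr <- double_robust_att(mt, co, c("W1", "W7"))
  expect_equal(dr$p1_bar, 0)
  expect_true(is.finite(dr$risk_difference))
})

test_that("the ridge fallback agrees with glm away from separation", {
  set.seed(507)
  x <- cbind(a = rnorm(4000), b = rbinom(4000, 1, 0.3))
  y <- rbinom(4000, 1, plogis(-1 + 0.8 * x[, "a"] - 0.5 * x[, "b"]))
  g <- glm(y ~ x, family = binomial())
  r <- ridge_logistic(x, y)
  expect_equal(unname(coef(g)), r, tolerance = 0.02)
})

test_that("marginal odds ratio follows its closed form", {
  expect_equal(marginal_odds_ratio(0.3, 0.3), 1)
  expect_equal(marginal_odds_ratio(0.0625, 0.10), 0.6, tolerance = 1e-12)
  expect_gt(marginal_odds_ratio(0.11, 0.10), marginal_odds_ratio(0.10, 0.10))
  expect_error(marginal_odds_ratio(0, 0.5), "clamp")
  expect_error(marginal_odds_ratio(0.5, 1), "clamp")
})

test_that("the marginal OR is attached on request", {
  s <- small_matched()
  dr <- double_robust_att(s$matched, s$cohort, c("W1", "W11"),
                          odds_ratio = TRUE)
  expect_gt(dr$marginal_odds_ratio, 0)
  or_hand <- (dr$p1_bar / (1 - dr$p1_bar)) / (dr$p0_bar / (1 - dr$p0_bar))
  expect_equal(dr$marginal_odds_ratio, or_hand)
})
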