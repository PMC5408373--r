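test_beta <- c(b0 = 0.1, b1 = 0.2, b2 = 0.3, b6 = 0.4, b7 = 0.5,
               b11 = 0.6, b13 = 0.7)
test_alpha <- c(a0 = -0.2, a1 = 0.6, a2 = 0.2, a3 = 0.3, a4 = 0.4,
                a5 = 0.5, a7 = 0.6, a9 = 0.7, a10 = 0.8, a11 = 0.9,
                a12 = 1.0, a13 = 1.1, a15 = 1.2)

test_that("linear_predictor evaluates intercept-only and single-term forms", {
  W <- cbind(W1 = c(0, 1, 2))
  expect_equal(linear_predictor(W, list(), intercept = 3), rep(3, 3))
  expect_equal(linear_predictor(W, list(term(2, basis_var("W1")))),
               c(0, 2, 4))
  expect_equal(plogis(linear_predictor(cbind(W1 = 1),
                                       list(term(2, basis_var("W1"))))),
               1 / (1 + exp(-2)))
})

test_that("scenario-B treatment predictor matches term-by-term hand evaluation", {
  spec <- scenario_spec("B", beta = test_beta, alpha = test_alpha,
                        gamma_z = -0.51)
  W <- oracle_unit()   # W1=W2=W3=W5=W6=1, W7=0.5, W10=1, W11=4, W12=9, W13=8
  hand <- 0.1 + 0.2 * 1 + 0.3 * 1 + 0.4 * 1 + 0.5 * 0.5 +
    0.6 * (sqrt(4) + 0.01 * 4^2) + 0.7 * sqrt(8) +
    0.2 * 0.4 * 1 * 1 +          # b1(0.4) W1 W2
    0.5 * 0.5 * 0.5 * 1 +        # b7(0.5) W7 W1
    0.3 * 0.7 * 0.5 * 1 +        # b2(0.7) W7 W2
    0.6 * 0.7 * sqrt(4) * (8 / 10)  # b11(0.7) sqrt(W11) (W13/10)
  expect_equal(treatment_logit(spec, W), hand, tolerance = 1e-12)
})

test_that("scenario-B outcome predictor matches term-by-term hand evaluation", {
  spec <- scenario_spec("B", beta = test_beta, alpha = test_alpha,
                        gamma_z = -0.51)
  W <- oracle_unit()
  hand <- -0.2 + 0.6 * 1 + 0.2 * 1 + 0.3 * 1 + 0.4 * 0 + 0.5 * 1 +
    0.6 * 0.5 + 0.7 * 0 + 0.8 * 1 + 1.2 * 0 +
    0.9 * log(4) + 1.0 * sqrt(9) + 1.1 * 8^(1 / 3) +
    (-0.51) * 1 +
    0.8 * 0.2 * 1 * 0.5 +        # a10(0.2) W10 W7
    0.4 * 0.7 * 0 * 1 +          # a4(0.7) W4 W2
    0.6 * 0.6 * 1 * 1 * 0.5      # a1(0.6) W1 W3 W7
  expect_equal(outcome_logit(spec, W, z = 1), hand, tolerance = 1e-12)
  # z = 0 removes exactly the treatment term
  expect_equal(outcome_logit(spec, W, z = 0), hand + 0.51, tolerance = 1e-12)
})

test_that("scenario-A predictors are the printed additive forms", {
  spec <- scenario_spec("A", beta = test_beta, alpha = test_alpha,
                        gamma_z = -0.51)
  W <- oracle_unit()
  expect_equal(treatment_logit(spec, W),
               0.1 + 0.2 + 0.3 + 0.4 + 0.5 * 0.5 + 0.6 * 4 + 0.7 * 8,
               tolerance = 1e-12)
  expect_equal(outcome_logit(spec, W, z = 1),
               -0.2 + 0.6 + 0.2 + 0.3 + 0 + 0.5 + 0.6 * 0.5 + 0 + 0.8 +
                 0.9 * 4 + 1.0 * 9 + 1.1 * 8 + 0 - 0.51,
               tolerance = 1e-12)
})

test_that("scenario B collapses to scenario A without its extra terms", {
  beta0 <- test_beta; beta0[c("b11", "b13")] <- 0
  alpha0 <- test_alpha; alpha0[c("a11", "a12", "a13")] <- 0
  specA <- scenario_spec("A", beta = beta0, alpha = alpha0)
  zero_nl <- as.list(setNames(rep(0, 12), c(
    "t_w11_nl", "t_w13_nl", "t_w1w2", "t_w7w1", "t_w7w2", "t_w11w13",
    "y_w11_log", "y_w12_sqrt", "y_w13_cbrt", "y_w10w7", "y_w4w2",
    "y_w1w3w7")))
  specB <- scenario_spec("B", beta = beta0, alpha = alpha0, nonlin = zero_nl)
  W <- draw_covariates(200, default_model(), seed = 106)
  expect_equal(treatment_logit(specB, W), treatment_logit(specA, W))
  expect_equal(outcome_logit(specB, W, z = 1), outcome_logit(specA, W, z = 1))
})

test_that("root and log bases reject invalid inputs naming unit and covariate", {
  spec <- scenario_spec("B", beta = test_beta, alpha = test_alpha)
  W <- oracle_unit()
  W[1, "W13"] <- -2
  expect_error(treatment_logit(spec, W), "W13 at unit 1")
  W2 <- oracle_unit()
  W2[1, "W11"] <- 0
  expect_error(outcome_logit(spec, W2, z = 0), "W11 at unit 1")
})

test_that("intercept calibration recovers closed-form solutions", {
  beta0 <- test_beta; beta0[] <- 0
  alpha0 <- test_alpha; alpha0[] <- 0
  half <- calibrate_scenario(
    scenario_spec("A", beta = beta0, alpha = alpha0, gamma_z = 0,
                  targets = c(exposure = 0.5, prevalence = 0.5)),
    default_model(), n_cal = 1000, seed = 107)
  expect_equal(half$beta[["b0"]], 0, tolerance = 1e-6)
  expect_equal(half$alpha[["a0"]], 0, tolerance = 1e-6)
  forty <- calibrate_scenario(
    scenario_spec("A", beta = beta0, alpha = alpha0, gamma_z = 0,
                  targets = c(exposure = 0.4, prevalence = 0.08)),
    default_model(), n_cal = 1000, seed = 108)
  expect_equal(forty$beta[["b0"]], qlogis(0.4), tolerance = 1e-6)
  expect_equal(forty$alpha[["a0"]], qlogis(0.08), tolerance = 1e-6)
})

test_that("calibration reports achieved marginals within tolerance", {
  spec <- calibrate_scenario(scenario_spec("A"), default_model())
  expect_true(spec$calibrated)
  expect_lt(abs(spec$achieved[["exposure"]] - 0.40), 0.003)
  expect_lt(abs(spec$achieved[["prevalence"]] - 0.08), 0.003)
})

test_that("shipped default scenarios carry the calibration routine's intercepts", {
  for (s in c("A", "B")) {
    shipped <- default_scenario(s)
    fresh <- calibrate_scenario(scenario_spec(s), default_model())
    expect_equal(shipped$beta[["b0"]], fresh$beta[["b0"]], tolerance = 1e-8)
    expect_equal(shipped$alpha[["a0"]], fresh$alpha[["a0"]], tolerance = 1e-8)
  }
})

test_that("unreachable targets raise a bracketing error", {
  beta_huge <- test_beta; beta_huge[] <- 0; beta_huge["b11"] <- 50
  spec <- scenario_spec("A", beta = beta_huge, alpha = test_alpha,
                        targets = c(exposure = 1e-9, prevalence = 0.08))
  expect_error(
    calibrate_scenario(spec, default_model(), n_cal = 500, seed = 109),
    "bracket")
})
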