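# Shared fixtures, built once per test run.

# calibrated default scenario A and default covariate model
fixture_env <- new.env(parent = emptyenv())

default_model <- function() {
  if (is.null(fixture_env$model)) fixture_env$model <- covariate_model()
  fixture_env$model
}

calibrated_A <- function() default_scenario("A")

# a small cohort + propensity fit + matched sample used by several files
small_matched <- function() {
  if (is.null(fixture_env$small)) {
    co <- generate_cohort(2000, calibrated_A(), default_model(), seed = 7)
    ps <- fit_propensity(co)
    mt <- nearest_neighbor_match(ps$ps_hat, co$Z, seed = 8)
    fixture_env$small <- list(cohort = co, ps = ps, matched = mt)
  }
  fixture_env$small
}

# hand-built covariate matrix for predictor oracles: one unit, all columns set
oracle_unit <- function() {
  W <- matrix(0, 1, 15, dimnames = list(NULL, paste0("W", 1:15)))
  W[1, ] <- c(1, 1, 1, 0, 1, 1, 0.5, -0.3, 0, 1, 4, 9, 8, 1, 0)
  W
}
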