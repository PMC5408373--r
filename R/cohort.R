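#' Threshold-assign binary events from probabilities
#'
#' Element \code{i} is 1 iff \code{p[i] > u[i]} with \code{u[i] ~ U(0,1)}
#' drawn independently, the thresholding mechanism used for both treatment
#' assignment and outcome occurrence.
#'
#' @param p probability vector, all in \[0, 1\].
#' @param seed optional integer seed; \code{NULL} uses the current stream.
#' @return binary (0/1) numeric vector of \code{length(p)}.
#' @export
assign_bernoulli <- function(p, seed = NULL) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("`p` must contain probabilities in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  as.numeric(p > runif(length(p)))
}

#' Generate one virtual cohort
#'
#' Draws covariates, computes the true propensity \code{p(Z)}, assigns
#' treatment, computes both potential-outcome probabilities (treatment
#' forced to 1 and to 0), assigns the potential outcomes \code{Y1} and
#' \code{Y0} with a shared uniform draw per unit, and sets the observed
#' outcome by consistency (\code{Y = Z*Y1 + (1-Z)*Y0}).
#'
#' @param n cohort size.
#' @param spec a calibrated [scenario_spec()].
#' @param model a [covariate_model()].
#' @param seed optional integer seed.
#' @return object of class \code{cohort}: list with the n x 15 covariate
#'   matrix \code{W}, vectors \code{Z}, \code{Y}, \code{Y1}, \code{Y0},
#'   true probabilities \code{p_treat}, \code{p_y1}, \code{p_y0}, and the
#'   generating scenario id.
#' @export
generate_cohort <- function(n, spec, model = covariate_model(), seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!isTRUE(spec$calibrated))
    stop("`spec` must be calibrated first; see calibrate_scenario()")
  if (!is.null(seed)) set.seed(seed)
  W <- draw_covariates(n, model)
  p_treat <- plogis(treatment_logit(spec, W))
  Z <- assign_bernoulli(p_treat)
  p_y1 <- plogis(outcome_logit(spec, W, z = 1))
  p_y0 <- plogis(outcome_logit(spec, W, z = 0))
  u <- runif(n)
  Y1 <- as.numeric(p_y1 > u)
  Y0 <- as.numeric(p_y0 > u)
  Y <- ifelse(Z == 1, Y1, Y0)
  structure(
    list(W = W, Z = Z, Y = Y, Y1 = Y1, Y0 = Y0,
         p_treat = p_treat, p_y1 = p_y1, p_y0 = p_y0,
         scenario = spec$scenario),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort (scenario ", x$scenario, "): ", length(x$Z), " units, ",
      sum(x$Z), " treated (", sprintf("%.1f%%", 100 * mean(x$Z)), "), ",
      "outcome prevalence ", sprintf("%.1f%%", 100 * mean(x$Y)), "\n",
      sep = "")
  invisible(x)
}

#' True average treatment effect in the treated (risk difference)
#'
#' Simulates a large population and averages, over the treated units, the
#' difference between the two potential-outcome probabilities
#' \code{p(Y=1|do(Z=1)) - p(Y=1|do(Z=0))}.  Negative under the default
#' protective effect.
#'
#' @param spec a calibrated [scenario_spec()].
#' @param model a [covariate_model()].
#' @param n_large simulation size (default 1e6).
#' @param seed optional integer seed.
#' @return scalar risk difference.
#' @export
true_att <- function(spec, model = covariate_model(), n_large = 1e6,
                     seed = NULL) {
  co <- generate_cohort(n_large, spec, model, seed = seed)
  treated <- co$Z == 1
  if (!any(treated)) stop("no treated units in the simulated population")
  mean(co$p_y1[treated] - co$p_y0[treated])
}

#' Write / read a cohort as CSV
#'
#' Columns \code{W1..W15, Z, Y, p_treat, Y1, Y0}, one row per unit.
#'
#' @param cohort a [generate_cohort()] result.
#' @param path file path.
#' @return \code{write_cohort_csv} returns \code{path} invisibly;
#'   \code{read_cohort_csv} returns a \code{cohort} object (without the
#'   potential-outcome probabilities, which are not part of the format).
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  df <- data.frame(cohort$W, Z = cohort$Z, Y = cohort$Y,
                   p_treat = cohort$p_treat, Y1 = cohort$Y1, Y0 = cohort$Y0)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path)
  wanted <- c(paste0("W", 1:15), "Z", "Y", "p_treat", "Y1", "Y0")
  missing <- setdiff(wanted, names(df))
  if (length(missing))
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "))
  structure(
    list(W = as.matrix(df[, paste0("W", 1:15)]),
         Z = df$Z, Y = df$Y, Y1 = df$Y1, Y0 = df$Y0,
         p_treat = df$p_treat, p_y1 = NULL, p_y0 = NULL,
         scenario = NA_character_),
    class = "cohort")
}
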