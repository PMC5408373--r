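#' Fit the propensity-score model
#'
#' Main-effects logistic regression of treatment on all 15 covariates
#' \code{W1..W15} (no interaction or transformed terms), mirroring the
#' common applied practice of a realistic rather than optimal propensity
#' model.  Non-convergence or (quasi-)separation is flagged rather than
#' raising, so a study replicate can be excluded and logged.
#'
#' @param cohort a [generate_cohort()] result (or any \code{cohort}).
#' @return object of class \code{propensity_fit}: \code{coefficients}
#'   (intercept + 15 slopes), \code{ps_hat} (fitted propensities, strictly
#'   inside (0,1)), \code{converged}, \code{separation}.
#' @export
fit_propensity <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(unique(cohort$Z)) < 2L)
    stop("both treatment groups must be non-empty")
  const <- apply(cohort$W, 2L, function(x) diff(range(x)) == 0)
  if (any(const))
    stop("constant covariate column(s): ",
         paste(colnames(cohort$W)[const], collapse = ", "))
  df <- data.frame(Z = cohort$Z, cohort$W)
  fit <- suppressWarnings(glm(Z ~ ., data = df, family = binomial()))
  ps <- fit$fitted.values
  eps <- .Machine$double.eps
  structure(
    list(coefficients = coef(fit),
         ps_hat = pmin(pmax(ps, eps), 1 - eps),
         converged = fit$converged,
         separation = any(ps < 1e-8 | ps > 1 - 1e-8)),
    class = "propensity_fit")
}

#' Greedy 1:1 nearest-neighbor matching without replacement
#'
#' Treated units are processed in a random (seeded) order; each is matched
#' to the not-yet-matched control unit minimizing the absolute difference
#' in estimated propensity score.  No caliper is applied, so when controls
#' outnumber treated every treated unit is matched (complete matching) and
#' the number of pairs is \code{J = min(n_treated, n_control)}.  Ties
#' between equidistant controls break to the lowest unit index.
#'
#' @param ps_hat estimated propensity scores.
#' @param Z binary treatment indicator vector, same length.
#' @param seed optional integer seed for the greedy processing order.
#' @return object of class \code{matched_sample}: data.frame \code{pairs}
#'   with columns \code{treated} and \code{control} (unit indices, each
#'   used at most once) and the pair count \code{J}.
#' @export
nearest_neighbor_match <- function(ps_hat, Z, seed = NULL) {
  stopifnot(length(ps_hat) == length(Z))
  treated <- which(Z == 1)
  control <- which(Z == 0)
  if (!length(treated) || !length(control))
    stop("both a treated and a control arm are required for matching")
  if (!is.null(seed)) set.seed(seed)
  order_t <- sample(treated)
  cps <- ps_hat[control]   # masked with +Inf once a control is used
  J <- min(length(treated), length(control))
  pair_t <- integer(J)
  pair_c <- integer(J)
  for (k in seq_len(J)) {
    t_idx <- order_t[k]
    j <- which.min(abs(cps - ps_hat[t_idx]))
    pair_t[k] <- t_idx
    pair_c[k] <- control[j]
    cps[j] <- Inf
  }
  structure(
    list(pairs = data.frame(treated = pair_t, control = pair_c), J = J),
    class = "matched_sample")
}

#' Percentage of the initial sample retained after matching
#'
#' \code{100 * 2J / n}: each of the J pairs keeps one treated and one
#' control unit.
#'
#' @param matched a [nearest_neighbor_match()] result.
#' @param n initial cohort size.
#' @return percentage in (0, 100\].
#' @export
retained_fraction <- function(matched, n) {
  stopifnot(inherits(matched, "matched_sample"), n >= 2 * matched$J)
  100 * 2 * matched$J / n
}

#' @export
print.matched_sample <- function(x, ...) {
  cat("Matched sample: ", x$J, " treated-control pairs\n", sep = "")
  invisible(x)
}
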