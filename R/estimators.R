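#' Crude matched ATT estimator
#'
#' Mean within-pair outcome difference over the J matched pairs:
#' \deqn{\widehat{ATT}_{crude} = (1/J) \sum_j (Y_{j1} - Y_{j0}).}
#'
#' @param matched a [nearest_neighbor_match()] result with \code{J >= 1}.
#' @param Y outcome vector of the full cohort (indexed by the pairs).
#' @return object of class \code{att_estimate}.
#' @export
crude_att <- function(matched, Y) {
  stopifnot(inherits(matched, "matched_sample"), matched$J >= 1L)
  # computed as the difference of arm means (algebraically the mean pair
  # difference) so the empty-adjustment double-robust estimate collapses to
  # it bit-exactly
  rd <- mean(Y[matched$pairs$treated]) - mean(Y[matched$pairs$control])
  new_att_estimate("crude", rd, threshold = NA_real_,
                   adjusted = character(), J = matched$J)
}

#' Double-robust (double-adjustment) ATT estimator
#'
#' Regression correction of residual confounding after matching: a
#' main-effects logistic outcome model is fitted separately within the
#' matched treated arm and the matched control arm, using the selected
#' (unbalanced) covariates as explanatory variables.  Both models then
#' predict the outcome probability for the matched \emph{treated} units --
#' the treated-arm model gives the potential outcome with treatment,
#' \eqn{\hat p_j(Y_1=1|Z=1)}, the control-arm model the potential outcome
#' without, \eqn{\hat p_j(Y_0=1|Z=1)} -- and the estimate is
#' \deqn{\widehat{ATT}_{DR} = (1/J)\sum_j [\hat p_j(Y_1=1|Z=1) -
#'   \hat p_j(Y_0=1|Z=1)].}
#'
#' With an empty adjustment set the within-arm models are intercept-only,
#' whose maximum-likelihood prediction is the arm proportion, so the
#' estimate collapses exactly to [crude_att()].  Within-arm separation or
#' non-convergence falls back to a weakly ridge-penalized fit (see
#' [ridge_logistic()]); an arm with a constant outcome predicts the
#' observed proportion.
#'
#' @param matched a [nearest_neighbor_match()] result.
#' @param cohort the cohort the pairs index into.
#' @param adjusted character vector of covariate names to adjust for
#'   (subset of \code{W1..W15}; possibly empty).
#' @param threshold optional SMD threshold recorded in the result.
#' @param odds_ratio also compute the marginal odds ratio from the two mean
#'   predicted probabilities (clamped off 0/1 by machine epsilon)?
#' @return object of class \code{att_estimate} with fields
#'   \code{risk_difference}, \code{p1_bar}, \code{p0_bar}, optionally
#'   \code{marginal_odds_ratio}, and \code{fallbacks} (number of arms that
#'   needed the penalized refit).
#' @export
double_robust_att <- function(matched, cohort, adjusted,
                              threshold = NA_real_, odds_ratio = FALSE) {
  stopifnot(inherits(matched, "matched_sample"), inherits(cohort, "cohort"),
            matched$J >= 1L)
  bad <- setdiff(adjusted, colnames(cohort$W))
  if (length(bad))
    stop("unknown adjusted covariate(s): ", paste(bad, collapse = ", "))
  ti <- matched$pairs$treated
  ci <- matched$pairs$control
  Yt <- cohort$Y[ti]
  Yc <- cohort$Y[ci]
  fallbacks <- 0L
  if (!length(adjusted)) {
    # intercept-only MLE predicts the arm proportion for every unit
    p1 <- rep(mean(Yt), matched$J)
    p0 <- rep(mean(Yc), matched$J)
  } else {
    Xt <- cohort$W[ti, adjusted, drop = FALSE]
    Xc <- cohort$W[ci, adjusted, drop = FALSE]
    m1 <- fit_arm_outcome(Yt, Xt)
    m0 <- fit_arm_outcome(Yc, Xc)
    p1 <- m1$predict(Xt)
    p0 <- m0$predict(Xt)
    fallbacks <- m1$fallback + m0$fallback
  }
  est <- new_att_estimate("double_robust", mean(p1) - mean(p0),
                          threshold = threshold, adjusted = adjusted,
                          J = matched$J, p1_bar = mean(p1),
                          p0_bar = mean(p0), fallbacks = fallbacks)
  if (odds_ratio) {
    eps <- .Machine$double.eps
    est$marginal_odds_ratio <- marginal_odds_ratio(
      pmin(pmax(est$p1_bar, eps), 1 - eps),
      pmin(pmax(est$p0_bar, eps), 1 - eps))
  }
  est
}

# One within-arm logistic outcome model; returns a prediction closure.
# Columns constant within the arm carry no information there and are
# dropped from that arm's model.
fit_arm_outcome <- function(Y, X) {
  if (length(unique(Y)) == 1L) {
    p <- mean(Y)
    return(list(predict = function(Xnew) rep(p, nrow(Xnew)), fallback = 0L))
  }
  keep <- apply(X, 2L, function(x) diff(range(x)) > 0)
  X <- X[, keep, drop = FALSE]
  if (!ncol(X)) {
    p <- mean(Y)
    return(list(predict = function(Xnew) rep(p, nrow(Xnew)), fallback = 0L))
  }
  df <- data.frame(.y = Y, X)
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  separated <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8) ||
    any(is.na(coef(fit))) || any(abs(coef(fit)) > 20, na.rm = TRUE)
  if (fit$converged && !separated) {
    list(predict = function(Xnew) {
      nd <- as.data.frame(Xnew[, colnames(X), drop = FALSE])
      unname(predict(fit, newdata = nd, type = "response"))
    }, fallback = 0L)
  } else {
    beta <- ridge_logistic(X, Y)
    list(predict = function(Xnew)
      plogis(drop(cbind(1, Xnew[, colnames(X), drop = FALSE]) %*% beta)),
      fallback = 1L)
  }
}

#' Weakly penalized logistic regression (separation fallback)
#'
#' Newton iterations on the logistic log-likelihood with a fixed small
#' ridge penalty \code{(lambda/2) * sum(slopes^2)} (intercept unpenalized).
#' Used only when an unpenalized within-arm fit fails to converge or is
#' (quasi-)separated; at \code{lambda = 1} the penalty is negligible
#' relative to the Fisher information of a ~2,000-unit arm but keeps
#' separated coefficients finite.
#'
#' @param X design matrix (no intercept column).
#' @param y binary response.
#' @param lambda ridge penalty on the slopes (default 1).
#' @param maxit,tol Newton iteration controls.
#' @return coefficient vector (intercept first).
#' @export
ridge_logistic <- function(X, y, lambda = 1, maxit = 200L, tol = 1e-10) {
  Xd <- cbind(1, as.matrix(X))
  p <- ncol(Xd)
  P <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    mu <- plogis(drop(Xd %*% beta))
    wt <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(Xd, y - mu) - P %*% beta
    H <- crossprod(Xd * wt, Xd) + P
    step <- solve(H, grad)
    # halve overlong steps for stability
    while (max(abs(step)) > 5) step <- step / 2
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  unname(beta)
}

#' Marginal odds ratio from mean potential-outcome probabilities
#'
#' Because the odds ratio is non-collapsible, a marginal OR is computed
#' from the two \emph{averaged} predicted probabilities:
#' \code{[p1/(1-p1)] / [p0/(1-p0)]}.
#'
#' @param p1_bar mean predicted probability under treatment, in (0,1).
#' @param p0_bar mean predicted probability under control, in (0,1).
#' @return positive scalar.
#' @export
#' @examples
#' marginal_odds_ratio(0.0625, 0.10)  # 0.6
marginal_odds_ratio <- function(p1_bar, p0_bar) {
  if (!is.finite(p1_bar) || !is.finite(p0_bar) ||
      p1_bar <= 0 || p1_bar >= 1 || p0_bar <= 0 || p0_bar >= 1)
    stop("mean probabilities must be strictly inside (0, 1); ",
         "clamp boundary values before calling")
  (p1_bar / (1 - p1_bar)) / (p0_bar / (1 - p0_bar))
}

new_att_estimate <- function(estimator, rd, threshold, adjusted, J,
                             p1_bar = NA_real_, p0_bar = NA_real_,
                             fallbacks = 0L) {
  stopifnot(rd >= -1, rd <= 1)
  structure(
    list(estimator = estimator, risk_difference = rd, threshold = threshold,
         adjusted = adjusted, J = J, p1_bar = p1_bar, p0_bar = p0_bar,
         fallbacks = fallbacks),
    class = "att_estimate")
}

#' @export
print.att_estimate <- function(x, ...) {
  cat(if (x$estimator == "crude") "Crude matched ATT"
      else "Double-robust ATT", ": risk difference ",
      sprintf("%.4f", x$risk_difference), sep = "")
  if (x$estimator != "crude")
    cat(" (threshold ", x$threshold, ", ", length(x$adjusted),
        " adjusted covariate(s))", sep = "")
  cat("\n")
  invisible(x)
}
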