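#' Standardized absolute mean difference
#'
#' \deqn{SMD = |m1 - m0| / \sqrt{(s1^2 + s0^2)/2}}
#' where \code{m1, m0} are the group means (proportions for binary
#' covariates) and \code{s1^2, s0^2} the unbiased (n-1) sample variances.
#' Sample-size free, non-negative and scale invariant.  If both variances
#' are zero the SMD is 0 when the means agree and \code{Inf} (with a
#' warning) when they differ.
#'
#' @param values_treated,values_control numeric vectors of the covariate in
#'   each group (non-empty).
#' @return non-negative scalar.
#' @export
#' @examples
#' smd(c(2, 4), c(1, 3))   # |3 - 2| / sqrt((2 + 2)/2) = 0.7071
smd <- function(values_treated, values_control) {
  if (!length(values_treated) || !length(values_control))
    stop("both groups must be non-empty")
  m1 <- mean(values_treated); m0 <- mean(values_control)
  v1 <- var(values_treated);  v0 <- var(values_control)
  if (is.na(v1)) v1 <- 0
  if (is.na(v0)) v0 <- 0
  pooled <- (v1 + v0) / 2
  if (pooled == 0) {
    if (m1 == m0) return(0)
    warning("zero variance in both groups with unequal means; SMD is Inf")
    return(Inf)
  }
  abs(m1 - m0) / sqrt(pooled)
}

#' Covariate balance in a matched sample
#'
#' Computes the SMD of each covariate \code{W1..W15} between the matched
#' treated and matched control units (covariates on their generated scale,
#' not the scenario basis terms).
#'
#' @param cohort the cohort the matched sample was drawn from.
#' @param matched a [nearest_neighbor_match()] result.
#' @return object of class \code{balance_table}: data.frame with one row
#'   per covariate and columns \code{covariate, mean_treated, mean_control,
#'   var_treated, var_control, smd}.
#' @export
balance_table <- function(cohort, matched) {
  stopifnot(inherits(cohort, "cohort"), inherits(matched, "matched_sample"),
            matched$J >= 1L)
  Wt <- cohort$W[matched$pairs$treated, , drop = FALSE]
  Wc <- cohort$W[matched$pairs$control, , drop = FALSE]
  tab <- data.frame(
    covariate = colnames(cohort$W),
    mean_treated = colMeans(Wt),
    mean_control = colMeans(Wc),
    var_treated = apply(Wt, 2L, var),
    var_control = apply(Wc, 2L, var),
    row.names = NULL)
  tab$smd <- vapply(seq_len(nrow(tab)), function(i)
    smd(Wt[, i], Wc[, i]), numeric(1))
  class(tab) <- c("balance_table", "data.frame")
  tab
}

#' Select covariates considered unbalanced at a threshold
#'
#' Returns the covariates whose SMD is greater than or equal to the
#' threshold (inclusive comparison).  Antitone in the threshold: a smaller
#' cutoff selects a superset.
#'
#' @param table a [balance_table()].
#' @param threshold positive SMD cutoff.
#' @return character vector of covariate names (possibly empty).
#' @export
select_unbalanced <- function(table, threshold) {
  stopifnot(inherits(table, "balance_table"), threshold > 0)
  table$covariate[table$smd >= threshold]
}

#' Default SMD threshold grid
#'
#' The 25 cutoffs 0.01, 0.02, ..., 0.25 examined when choosing covariates
#' for double-adjustment.
#'
#' @return numeric vector of length 25.
#' @export
smd_thresholds <- function() {
  round(seq(0.01, 0.25, by = 0.01), 2)
}
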