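#' Covariate model for virtual perioperative cohorts
#'
#' Describes how the 15 explanatory covariates \code{W1..W15} are generated.
#' Fourteen correlated standard normals are drawn first (one latent variable
#' for each of \code{W1..W13} and \code{W15}) and then transformed
#' marginally: binary covariates are obtained by dichotomizing the latent
#' normal at the quantile matching a target prevalence; continuous
#' covariates by affine or exponential (log-normal) maps.  Covariates that
#' later enter square roots, logs or fractional powers (\code{W11},
#' \code{W12}, \code{W13}) use the exponential map so they are strictly
#' positive.  \code{W14} is not drawn: it is a deterministic composite of
#' the other covariates (a cardiac-risk-index-like indicator), computed
#' after the rest.
#'
#' @param correlation 14x14 symmetric positive-definite correlation matrix
#'   of the latent normals, unit diagonal.  Rows/columns follow the order
#'   \code{W1..W13, W15}.  Default: block-exchangeable structure with
#'   within-block correlation 0.3 and between-block correlation 0.1 (see
#'   [default_correlation()]).
#' @param transforms named list of 14 per-covariate transform rules (names
#'   \code{W1..W13}, \code{W15}).  Each rule is a list with a \code{type}
#'   field: \code{"binary"} (field \code{prevalence}), \code{"normal"}
#'   (fields \code{mean}, \code{sd}) or \code{"lognormal"} (fields
#'   \code{scale}, \code{sigma}; the covariate is
#'   \code{scale * exp(sigma * z)}).
#' @param composite_rule function of the partially filled n x 15 covariate
#'   matrix returning the \code{W14} column.  Default: indicator that at
#'   least 2 of the binary risk factors \code{W1, W2, W3, W9, W10} are
#'   present.
#'
#' @return An object of class \code{covariate_model}.
#' @export
#' @examples
#' m <- covariate_model()
#' W <- draw_covariates(1000, m, seed = 1)
#' colMeans(W[, c("W1", "W2")])
covariate_model <- function(correlation = default_correlation(),
                            transforms = default_transforms(),
                            composite_rule = default_composite_rule()) {
  correlation <- as.matrix(correlation)
  if (nrow(correlation) != 14L || ncol(correlation) != 14L)
    stop("`correlation` must be a 14x14 matrix (latent normals for W1..W13, W15)")
  if (max(abs(correlation - t(correlation))) > 1e-8)
    stop("`correlation` must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-8)
    stop("`correlation` must have unit diagonal")
  ch <- tryCatch(chol(correlation), error = function(e) NULL)
  if (is.null(ch))
    stop("`correlation` matrix is not positive definite")
  if (!setequal(names(transforms), latent_covariate_names()))
    stop("`transforms` must be a named list covering exactly W1..W13 and W15")
  structure(
    list(correlation = correlation,
         chol = ch,
         transforms = transforms[latent_covariate_names()],
         composite_rule = composite_rule),
    class = "covariate_model")
}

#' Names of the 14 directly generated covariates (all but the composite W14)
#' @keywords internal
latent_covariate_names <- function() {
  setdiff(paste0("W", 1:15), "W14")
}

#' Default latent correlation structure
#'
#' Block-exchangeable correlation among the 14 latent normals, "correlated
#' by different degrees": three clinical blocks with correlation
#' \code{within} (default 0.3) inside a block and \code{between} (default
#' 0.05) across blocks -- a treatment-determinant cluster (W1, W2, W6,
#' W7), a biomarker cluster (W11, W12, W13) and an outcome-risk-factor
#' cluster (W3, W4, W5, W9, W10, W15).  Two refinements give the noise
#' variables the imbalance-at-risk character of real covariates: W8 (a
#' marker with no causal role) is correlated 0.28 with each member of the
#' treatment-determinant cluster, and the two renal/biomarker variables
#' W11 and W12 are correlated 0.6 as companion markers of the same organ
#' system.
#'
#' @param within within-block correlation (default 0.3).
#' @param between between-block correlation (default 0.05).
#' @param r_noise correlation of W8 with the treatment-determinant block
#'   (default 0.28).
#' @param r_biomarkers correlation between W11 and W12 (default 0.6).
#' @return 14x14 correlation matrix with dimnames \code{W1..W13, W15}.
#' @export
default_correlation <- function(within = 0.3, between = 0.05,
                                r_noise = 0.28, r_biomarkers = 0.6) {
  nm <- latent_covariate_names()
  blocks <- list(c("W1", "W2", "W6", "W7"),
                 c("W11", "W12", "W13"),
                 c("W3", "W4", "W5", "W9", "W10", "W15"))
  R <- matrix(between, 14, 14, dimnames = list(nm, nm))
  for (b in blocks) R[b, b] <- within
  R["W8", blocks[[1]]] <- r_noise
  R[blocks[[1]], "W8"] <- r_noise
  R["W11", "W12"] <- r_biomarkers
  R["W12", "W11"] <- r_biomarkers
  diag(R) <- 1
  R
}

#' Default marginal transforms for the 14 generated covariates
#'
#' Mixed binary/continuous marginals with prevalences and scales in the
#' range of perioperative risk factors: binary comorbidity indicators
#' (prevalence 0.10--0.35), two standardized continuous markers (W7 and the
#' noise variable W8) and three strictly positive biomarkers generated as
#' log-normals: W11 (creatinine-like, median 1), W12 (biomarker, median 2)
#' and W13 (age in decades, median 6.5).  The log-normal covariates are the
#' ones entering roots/logs in the non-linear scenario, hence the positive
#' support.
#'
#' @return named list of transform rules (see [covariate_model()]).
#' @export
default_transforms <- function() {
  list(
    W1  = list(type = "binary", prevalence = 0.30),
    W2  = list(type = "binary", prevalence = 0.20),
    W3  = list(type = "binary", prevalence = 0.15),
    W4  = list(type = "binary", prevalence = 0.25),
    W5  = list(type = "binary", prevalence = 0.10),
    W6  = list(type = "binary", prevalence = 0.35),
    W7  = list(type = "normal", mean = 0, sd = 1),
    W8  = list(type = "normal", mean = 0, sd = 1),
    W9  = list(type = "binary", prevalence = 0.20),
    W10 = list(type = "binary", prevalence = 0.15),
    W11 = list(type = "lognormal", scale = 1.0, sigma = 0.5),
    W12 = list(type = "lognormal", scale = 2.0, sigma = 0.4),
    W13 = list(type = "lognormal", scale = 6.5, sigma = 0.18),
    W15 = list(type = "binary", prevalence = 0.30)
  )
}

#' Default composite rule for W14
#'
#' W14 mimics a revised-cardiac-risk-index-style score: the indicator that
#' at least two of the binary risk factors W2, W3, W5, W9, W10 are present.
#' It enters no treatment or outcome model (a noise variable), but is
#' correlated with true confounders through its components and therefore at
#' risk of imbalance.
#'
#' @return function of the n x 15 covariate matrix returning the W14 column.
#' @export
default_composite_rule <- function() {
  function(W) {
    as.numeric(W[, "W2"] + W[, "W3"] + W[, "W5"] + W[, "W9"] + W[, "W10"] >= 2)
  }
}

apply_transform <- function(z, rule, name) {
  switch(rule$type,
    binary = as.numeric(z > qnorm(1 - rule$prevalence)),
    normal = rule$mean + rule$sd * z,
    lognormal = rule$scale * exp(rule$sigma * z),
    stop("unknown transform type '", rule$type, "' for ", name))
}

#' Draw the covariate matrix
#'
#' Draws \code{n} units: 14 correlated standard normals are transformed to
#' \code{W1..W13, W15} per the model's marginal rules, then \code{W14} is
#' filled in by the composite rule.
#'
#' @param n number of units (>= 2).
#' @param model a [covariate_model()].
#' @param seed optional integer seed; \code{NULL} uses the current RNG
#'   stream.
#' @return n x 15 numeric matrix with columns \code{W1..W15}.
#' @export
draw_covariates <- function(n, model = covariate_model(), seed = NULL) {
  stopifnot(inherits(model, "covariate_model"), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  Zlat <- matrix(rnorm(n * 14L), nrow = n) %*% model$chol
  W <- matrix(NA_real_, n, 15L, dimnames = list(NULL, paste0("W", 1:15)))
  nm <- latent_covariate_names()
  for (j in seq_along(nm)) {
    W[, nm[j]] <- apply_transform(Zlat[, j], model$transforms[[nm[j]]], nm[j])
  }
  W[, "W14"] <- model$composite_rule(W)
  W
}

#' @export
print.covariate_model <- function(x, ...) {
  types <- vapply(x$transforms, `[[`, "", "type")
  cat("Covariate model: 14 correlated latent normals -> W1..W13, W15; ",
      "W14 composite\n", sep = "")
  cat("  binary: ", paste(names(types)[types == "binary"], collapse = " "),
      "\n  continuous: ",
      paste(names(types)[types != "binary"], collapse = " "), "\n", sep = "")
  invisible(x)
}
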