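#' Write / read a scenario + covariate-model configuration file
#'
#' Round-trips the full data-generating configuration (scenario
#' coefficients, non-linear term coefficients, calibration targets, the
#' marginal transforms and the latent correlation matrix) through a YAML
#' file, so a study can be re-run from a plain-text config.  The
#' correlation matrix can be stored inline (list of rows, the default) or
#' as a path to a headerless CSV matrix.
#'
#' @param spec a [scenario_spec()].
#' @param model a [covariate_model()].
#' @param path YAML file path.
#' @param correlation_csv optional path to write the correlation matrix as
#'   CSV instead of inlining it (stored relative to the YAML file's
#'   directory if relative).
#' @return \code{write_scenario_config} returns \code{path} invisibly;
#'   \code{read_scenario_config} returns \code{list(spec, model)}.  Custom
#'   composite rules are not serialized: the reader restores the default
#'   composite rule.
#' @export
write_scenario_config <- function(spec, model, path, correlation_csv = NULL) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(model, "covariate_model"))
  cfg <- list(
    scenario = list(
      id = spec$scenario,
      beta = as.list(spec$beta),
      alpha = as.list(spec$alpha),
      gamma_z = spec$gamma_z,
      nonlin = spec$nonlin,
      targets = as.list(spec$targets),
      calibrated = spec$calibrated),
    covariates = list(
      transforms = model$transforms,
      correlation = if (is.null(correlation_csv)) {
        lapply(seq_len(nrow(model$correlation)),
               function(i) unname(model$correlation[i, ]))
      } else {
        write.table(model$correlation,
                    file.path(dirname(path), correlation_csv),
                    sep = ",", row.names = FALSE, col.names = FALSE)
        list(csv = correlation_csv)
      }))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sc <- cfg$scenario
  spec <- scenario_spec(
    scenario = sc$id,
    beta = unlist(sc$beta),
    alpha = unlist(sc$alpha),
    gamma_z = sc$gamma_z,
    targets = unlist(sc$targets),
    nonlin = sc$nonlin)
  spec$calibrated <- isTRUE(sc$calibrated)
  corr <- cfg$covariates$correlation
  R <- if (!is.null(corr$csv)) {
    as.matrix(read.csv(file.path(dirname(path), corr$csv), header = FALSE))
  } else {
    do.call(rbind, corr)
  }
  dimnames(R) <- list(latent_covariate_names(), latent_covariate_names())
  model <- covariate_model(correlation = R,
                           transforms = cfg$covariates$transforms)
  list(spec = spec, model = model)
}
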