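#' Summary plots of a Monte Carlo study
#'
#' Reproduce the study's four standard displays from a [run_study()]
#' result: the distribution of ATT estimates across the threshold grid
#' (median with 2.5th/97.5th percentiles), the relative bias curve, the
#' MSE curve, and the per-covariate residual-imbalance (SMD) distribution
#' after matching.  The crude estimator is drawn as a reference band/line.
#'
#' @param result a \code{study_result} from [run_study()].
#' @param scenario scenario id to plot (default: first in the result).
#' @return a \code{ggplot} object.
#' @name study-plots
NULL

pick_scenario <- function(result, scenario) {
  stopifnot(inherits(result, "study_result"))
  if (is.null(scenario)) names(result$att_true)[1] else scenario
}

#' @rdname study-plots
#' @export
plot_estimates <- function(result, scenario = NULL) {
  sc <- pick_scenario(result, scenario)
  sm <- result$summary[result$summary$scenario == sc, ]
  dr <- sm[sm$estimator == "double_robust", ]
  crude <- sm[sm$estimator == "crude", ]
  ggplot2::ggplot(dr, ggplot2::aes(x = .data$threshold, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = result$att_true[[sc]],
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = crude$mean, colour = "firebrick") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$p2.5,
                                          ymax = .data$p97.5)) +
    ggplot2::labs(x = "SMD threshold", y = "Estimated ATT (risk difference)",
                  title = sprintf(
                    "Scenario %s: ATT estimates by SMD threshold", sc),
                  subtitle = "dashed: true ATT; red: crude estimator mean") +
    ggplot2::theme_minimal()
}

#' @rdname study-plots
#' @export
plot_relative_bias <- function(result, scenario = NULL) {
  sc <- pick_scenario(result, scenario)
  sm <- result$summary[result$summary$scenario == sc, ]
  dr <- sm[sm$estimator == "double_robust", ]
  crude <- sm[sm$estimator == "crude", ]
  ggplot2::ggplot(dr, ggplot2::aes(x = .data$threshold,
                                   y = .data$relative_bias)) +
    ggplot2::geom_hline(yintercept = crude$relative_bias,
                        colour = "firebrick") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "SMD threshold", y = "Relative bias (%)",
                  title = sprintf("Scenario %s: relative bias", sc),
                  subtitle = "red: crude estimator") +
    ggplot2::theme_minimal()
}

#' @rdname study-plots
#' @export
plot_mse <- function(result, scenario = NULL) {
  sc <- pick_scenario(result, scenario)
  sm <- result$summary[result$summary$scenario == sc, ]
  dr <- sm[sm$estimator == "double_robust", ]
  crude <- sm[sm$estimator == "crude", ]
  ggplot2::ggplot(dr, ggplot2::aes(x = .data$threshold, y = .data$mse)) +
    ggplot2::geom_hline(yintercept = crude$mse, colour = "firebrick") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "SMD threshold", y = "Mean squared error",
                  title = sprintf("Scenario %s: MSE", sc),
                  subtitle = "red: crude estimator") +
    ggplot2::theme_minimal()
}

#' @rdname study-plots
#' @export
plot_balance <- function(result, scenario = NULL) {
  sc <- pick_scenario(result, scenario)
  bal <- result$balance[result$balance$scenario == sc, ]
  long <- data.frame(
    covariate = rep(paste0("W", 1:15), each = nrow(bal)),
    smd = unlist(bal[paste0("W", 1:15)], use.names = FALSE))
  long$covariate <- factor(long$covariate, levels = paste0("W", 1:15))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$covariate, y = .data$smd)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::geom_hline(yintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "SMD after matching",
                  title = sprintf(
                    "Scenario %s: residual imbalance across replicates", sc)) +
    ggplot2::theme_minimal()
}
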