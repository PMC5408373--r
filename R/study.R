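#' Monte Carlo study configuration
#'
#' @param n_units cohort size per replicate (default 5000).
#' @param n_replicates number of replicates (default 200, a desk-scale
#'   profile; the reference design of 1000 is available by setting it).
#' @param scenarios character vector of scenario ids ("A", "B") or a named
#'   list of [scenario_spec()] objects (calibrated or not; uncalibrated
#'   specs are calibrated at run time).
#' @param thresholds SMD threshold grid (default [smd_thresholds()]).
#' @param seed master seed; per-replicate seeds are derived from it
#'   deterministically.
#' @param n_true simulation size for the true ATT (default 1e6).
#' @param n_cal calibration cohort size (default 2e5).
#' @param out_dir optional directory for CSV/log outputs of [run_study()].
#' @return object of class \code{study_config}.
#' @export
study_config <- function(n_units = 5000, n_replicates = 200,
                         scenarios = c("A", "B"),
                         thresholds = smd_thresholds(),
                         seed = 1L, n_true = 1e6, n_cal = 2e5,
                         out_dir = NULL) {
  stopifnot(n_units >= 10, n_replicates >= 1, length(thresholds) >= 1,
            all(thresholds > 0))
  structure(
    list(n_units = n_units, n_replicates = n_replicates,
         scenarios = scenarios, thresholds = sort(thresholds),
         seed = as.integer(seed), n_true = n_true, n_cal = n_cal,
         out_dir = out_dir),
    class = "study_config")
}

#' Run one study replicate
#'
#' Generates a cohort, fits the propensity model, matches 1:1 without
#' caliper, computes the balance table, the crude estimate and one
#' double-robust estimate per SMD threshold (within-arm fits are cached
#' across thresholds selecting the same covariate set).
#'
#' @param spec calibrated [scenario_spec()].
#' @param model [covariate_model()].
#' @param n_units cohort size.
#' @param thresholds SMD threshold grid.
#' @param seed replicate seed (drives cohort generation, treatment/outcome
#'   assignment and the greedy matching order).
#' @return list with \code{estimates} (named vector: \code{crude},
#'   \code{thr_0.01}, ...), \code{retained} (percentage), \code{smd}
#'   (named per-covariate vector), \code{n_adjusted} (covariates selected
#'   per threshold), \code{excluded} flag with \code{reason}, and
#'   \code{fallbacks} (within-arm penalized refits).
#' @export
run_replicate <- function(spec, model = covariate_model(), n_units = 5000,
                          thresholds = smd_thresholds(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_cohort(n_units, spec, model)
  fit <- fit_propensity(cohort)
  if (!fit$converged || fit$separation) {
    return(list(estimates = NULL, retained = NA_real_, smd = NULL,
                n_adjusted = NULL, excluded = TRUE,
                reason = if (!fit$converged) "propensity fit did not converge"
                         else "propensity fit separated",
                fallbacks = 0L))
  }
  matched <- nearest_neighbor_match(fit$ps_hat, cohort$Z)
  bal <- balance_table(cohort, matched)
  smds <- setNames(bal$smd, bal$covariate)
  ests <- numeric(1L + length(thresholds))
  names(ests) <- c("crude", sprintf("thr_%.2f", thresholds))
  ests[["crude"]] <- crude_att(matched, cohort$Y)$risk_difference
  n_adj <- integer(length(thresholds))
  cache <- list()
  fallbacks <- 0L
  for (i in seq_along(thresholds)) {
    sel <- select_unbalanced(bal, thresholds[i])
    key <- if (length(sel)) paste(sel, collapse = "|") else "<none>"
    if (is.null(cache[[key]])) {
      dr <- double_robust_att(matched, cohort, sel,
                              threshold = thresholds[i])
      fallbacks <- fallbacks + dr$fallbacks
      cache[[key]] <- dr$risk_difference
    }
    ests[i + 1L] <- cache[[key]]
    n_adj[i] <- length(sel)
  }
  list(estimates = ests,
       retained = retained_fraction(matched, n_units),
       smd = smds, n_adjusted = n_adj,
       excluded = FALSE, reason = NA_character_, fallbacks = fallbacks)
}

#' Relative bias of an estimator (percent)
#'
#' \code{100 * |mean(estimates) - att_true| / |att_true|}.  The absolute
#' value in the denominator keeps the metric non-negative for protective
#' (negative) true effects.
#'
#' @param estimates vector of per-replicate estimates.
#' @param att_true true ATT (non-zero; for a null effect use absolute
#'   bias instead).
#' @return percentage.
#' @export
relative_bias <- function(estimates, att_true) {
  if (att_true == 0)
    stop("relative bias is undefined for att_true = 0; use absolute bias")
  100 * abs(mean(estimates) - att_true) / abs(att_true)
}

#' Mean squared error about the true ATT
#'
#' \code{mean((estimates - att_true)^2)}.
#'
#' @inheritParams relative_bias
#' @return non-negative scalar.
#' @export
mse <- function(estimates, att_true) {
  stopifnot(length(estimates) >= 1)
  mean((estimates - att_true)^2)
}

#' Percentage of biased estimates per deviation margin
#'
#' For each margin m (percent), the share of replicates whose estimate
#' deviates from the truth by strictly more than m percent of \code{|att_true|}.
#' Non-increasing in the margin.
#'
#' @inheritParams relative_bias
#' @param margins deviation margins in percent (default 25, 50, 75, 100).
#' @return named numeric vector of percentages.
#' @export
pct_biased <- function(estimates, att_true, margins = c(25, 50, 75, 100)) {
  if (att_true == 0) stop("pct_biased is undefined for att_true = 0")
  dev <- 100 * abs(estimates - att_true) / abs(att_true)
  setNames(vapply(margins, function(m) 100 * mean(dev > m), numeric(1)),
           paste0("gt", margins))
}

#' Run the full Monte Carlo study
#'
#' For each scenario: calibrates it (if needed), computes the true ATT by
#' large-sample potential-outcome simulation, runs \code{n_replicates}
#' replicates with seeds derived from the master seed, and aggregates the
#' crude and per-threshold double-robust estimates into the evaluation
#' metrics (mean, 2.5th/97.5th percentiles, relative bias, MSE, percent of
#' estimates deviating by >25/50/75/100%).  Replicates whose propensity
#' fit fails are excluded from aggregation and counted.
#'
#' @param config a [study_config()].
#' @param model a [covariate_model()].
#' @param progress print a line per scenario?
#' @return object of class \code{study_result}: list with \code{summary}
#'   (one row per scenario x estimator), \code{replicates} (long
#'   data.frame of all estimates), \code{balance} (per-replicate SMDs),
#'   \code{retained} (per-replicate retention), \code{att_true} (named per
#'   scenario), \code{excluded} (data.frame of exclusions) and the config.
#'   If \code{config$out_dir} is set, writes \code{replicates.csv},
#'   \code{summary.csv}, \code{balance.csv} and \code{run_log.txt} there.
#' @export
run_study <- function(config = study_config(), model = covariate_model(),
                      progress = interactive()) {
  stopifnot(inherits(config, "study_config"))
  specs <- resolve_scenarios(config$scenarios)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_replicates)
  all_reps <- list(); all_bal <- list(); all_ret <- list()
  summaries <- list(); exclusions <- list()
  att_true_by_scenario <- numeric(0)
  for (sc_name in names(specs)) {
    spec <- specs[[sc_name]]
    if (!isTRUE(spec$calibrated))
      spec <- calibrate_scenario(spec, model, n_cal = config$n_cal,
                                 seed = config$seed)
    att0 <- true_att(spec, model, n_large = config$n_true,
                     seed = config$seed)
    att_true_by_scenario[sc_name] <- att0
    if (progress)
      cat(sprintf("scenario %s: true ATT %.4f; running %d replicates\n",
                  sc_name, att0, config$n_replicates))
    reps <- lapply(seq_len(config$n_replicates), function(i)
      run_replicate(spec, model, config$n_units, config$thresholds,
                    seed = rep_seeds[i]))
    keep <- !vapply(reps, `[[`, logical(1), "excluded")
    if (any(!keep))
      exclusions[[sc_name]] <- data.frame(
        scenario = sc_name, replicate = which(!keep),
        reason = vapply(reps[!keep], `[[`, character(1), "reason"))
    est_mat <- do.call(rbind, lapply(reps[keep], `[[`, "estimates"))
    all_reps[[sc_name]] <- data.frame(
      scenario = sc_name,
      replicate = rep(which(keep), ncol(est_mat)),
      estimator = rep(colnames(est_mat), each = nrow(est_mat)),
      estimate = as.vector(est_mat))
    all_bal[[sc_name]] <- data.frame(
      scenario = sc_name, replicate = which(keep),
      do.call(rbind, lapply(reps[keep], `[[`, "smd")))
    all_ret[[sc_name]] <- data.frame(
      scenario = sc_name, replicate = which(keep),
      retained = vapply(reps[keep], `[[`, numeric(1), "retained"))
    summaries[[sc_name]] <- summarize_estimates(est_mat, att0, sc_name,
                                                config$thresholds)
    summaries[[sc_name]]$n_excluded <- sum(!keep)
    summaries[[sc_name]]$mean_retained <-
      mean(all_ret[[sc_name]]$retained)
  }
  res <- structure(
    list(summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
         replicates = do.call(rbind, c(all_reps, make.row.names = FALSE)),
         balance = do.call(rbind, c(all_bal, make.row.names = FALSE)),
         retained = do.call(rbind, c(all_ret, make.row.names = FALSE)),
         excluded = if (length(exclusions))
           do.call(rbind, c(exclusions, make.row.names = FALSE))
           else NULL,
         att_true = att_true_by_scenario,
         config = config),
    class = "study_result")
  frac_excluded <- if (is.null(res$excluded)) 0 else
    nrow(res$excluded) / (config$n_replicates * length(specs))
  if (frac_excluded > 0.05)
    warning(sprintf("%.1f%% of replicates were excluded (propensity-fit %s",
                    100 * frac_excluded, "failures); see $excluded"))
  if (!is.null(config$out_dir)) write_study_outputs(res, rep_seeds)
  res
}

resolve_scenarios <- function(scenarios) {
  if (is.character(scenarios)) {
    specs <- lapply(scenarios, default_scenario)
    names(specs) <- scenarios
  } else {
    specs <- scenarios
    if (is.null(names(specs)))
      names(specs) <- vapply(specs, `[[`, "", "scenario")
  }
  stopifnot(all(vapply(specs, inherits, logical(1), "scenario_spec")))
  specs
}

summarize_estimates <- function(est_mat, att0, sc_name, thresholds) {
  per_col <- function(e) {
    q <- quantile(e, c(0.025, 0.975), names = FALSE)
    c(mean = mean(e), p2.5 = q[1], p97.5 = q[2],
      relative_bias = relative_bias(e, att0), mse = mse(e, att0),
      pct_biased(e, att0))
  }
  stats <- t(apply(est_mat, 2L, per_col))
  data.frame(
    scenario = sc_name,
    estimator = ifelse(colnames(est_mat) == "crude", "crude",
                       "double_robust"),
    threshold = c(NA_real_, thresholds),
    att_true = att0,
    stats,
    row.names = NULL, check.names = FALSE)
}

write_study_outputs <- function(res, rep_seeds) {
  dir.create(res$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(res$config$out_dir, f)
  write.csv(res$replicates, p("replicates.csv"), row.names = FALSE)
  write.csv(res$summary, p("summary.csv"), row.names = FALSE)
  write.csv(res$balance, p("balance.csv"), row.names = FALSE)
  log_lines <- c(
    sprintf("master seed: %d", res$config$seed),
    sprintf("replicate seeds: %s", paste(rep_seeds, collapse = " ")),
    sprintf("true ATT: %s",
            paste(names(res$att_true), sprintf("%.5f", res$att_true),
                  sep = "=", collapse = " ")),
    if (is.null(res$excluded)) "exclusions: none" else
      paste("excluded:", nrow(res$excluded), "replicate(s):",
            paste(res$excluded$scenario, res$excluded$replicate,
                  res$excluded$reason, collapse = "; ")))
  writeLines(log_lines, p("run_log.txt"))
  invisible(res)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Monte Carlo study: ", x$config$n_replicates, " replicates x ",
      x$config$n_units, " units; scenarios ",
      paste(names(x$att_true), collapse = ", "), "\n", sep = "")
  for (s in names(x$att_true)) {
    sm <- x$summary[x$summary$scenario == s, ]
    crude <- sm[sm$estimator == "crude", ]
    best <- sm[which.min(sm$mse), ]
    cat(sprintf(
      "  %s: true ATT %.4f | crude rel. bias %.1f%% | min MSE %.2e at %s\n",
      s, x$att_true[[s]], crude$relative_bias, best$mse,
      if (is.na(best$threshold)) "crude" else
        sprintf("threshold %.2f", best$threshold)))
  }
  invisible(x)
}
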