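# Orchestration of the full two-sample analysis flow (estimator battery,
# heterogeneity, sensitivity filters, multivariable mediation), the
# bidirectional (role-swapped) analysis, the non-centrality-parameter power
# calculation, and the estimator benchmark grid.

.all_methods <- c("ivw_fixed", "ivw_random", "ivw_2nd", "egger",
                  "weighted_median", "mbe", "ivw_correlated")

#' Analysis configuration for the two-sample pipeline
#'
#' @param exposure,outcome [summary_table()]s (or paths readable by
#'   [read_summary_stats()]; paths are read with canonical headers).
#' @param mediators optional named list of [summary_table()]s: used both
#'   for the mediator-exclusion sensitivity filter and for multivariable
#'   MR.
#' @param ld optional [ld_info()]; enables LD pruning of the exposure
#'   instruments and the correlated-instrument estimator.
#' @param methods estimator subset (default: all applicable).
#' @param q_level optional `"L1"`/`"L2"`/`"L3"` per-instrument Q exclusion.
#' @param mediator_p p-value threshold for the mediator-exclusion filter
#'   (default 0.05).
#' @param phi bandwidth multiplier for the mode-based estimate.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param r2_threshold LD-pruning threshold (default 0.05).
#' @param palindromic_policy passed to [harmonize()].
#' @param sd_exposure_label label for OR reporting (e.g. "6.5 cm").
#' @param seed global seed; every stochastic step derives its own stream
#'   from it.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(exposure, outcome, mediators = NULL,
                            ld = NULL, methods = NULL, q_level = NULL,
                            mediator_p = 0.05, phi = 1, n_boot = 1000L,
                            r2_threshold = 0.05,
                            palindromic_policy = "infer_by_eaf",
                            sd_exposure_label = NULL, seed) {
  if (is.character(exposure)) {
    exposure <- read_summary_stats(exposure, trait_type = "quantitative")
  }
  if (is.character(outcome)) {
    outcome <- read_summary_stats(outcome, trait_type = "binary")
  }
  stopifnot(inherits(exposure, "summary_table"),
            inherits(outcome, "summary_table"))
  methods <- methods %||%
    setdiff(.all_methods, if (is.null(ld)) "ivw_correlated" else character(0))
  bad <- setdiff(methods, .all_methods)
  if (length(bad) > 0L) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("ivw_correlated" %in% methods && is.null(ld)) {
    stop("ivw_correlated requires LD information", call. = FALSE)
  }
  if (!is.null(q_level)) q_level <- match.arg(q_level, c("L1", "L2", "L3"))
  structure(list(exposure = exposure, outcome = outcome,
                 mediators = mediators, ld = ld, methods = methods,
                 q_level = q_level, mediator_p = mediator_p, phi = phi,
                 n_boot = as.integer(n_boot),
                 r2_threshold = r2_threshold,
                 palindromic_policy = palindromic_policy,
                 sd_exposure_label = sd_exposure_label, seed = seed),
            class = "analysis_config")
}

fit_methods <- function(h, cfg) {
  ests <- list()
  for (m in cfg$methods) {
    ests[[m]] <- switch(m,
      ivw_fixed = ivw(h, "fixed"),
      ivw_random = ivw(h, "random"),
      ivw_2nd = ivw(h, "second_order"),
      egger = if (nrow(h) >= 3L) egger_regression(h) else NULL,
      weighted_median = if (nrow(h) >= 3L)
        weighted_median(h, n_boot = cfg$n_boot,
                        seed = cfg$seed + 1L) else NULL,
      mbe = if (nrow(h) >= 3L)
        mode_based_estimate(h, phi = cfg$phi, n_boot = cfg$n_boot,
                            seed = cfg$seed + 2L) else NULL,
      ivw_correlated = ivw_correlated(h, cfg$ld))
  }
  Filter(Negate(is.null), ests)
}

#' Run the full two-sample analysis pipeline
#'
#' Stage order: LD-prune the exposure instruments (when LD is supplied),
#' harmonise exposure/outcome/mediators, fit the requested estimator
#' battery, compute heterogeneity diagnostics and funnel data, apply the
#' per-instrument Q filter and the mediator-exclusion filter (when
#' configured), and run multivariable MR with mediation decomposition per
#' mediator. Every stage appends a log line with instrument counts; the
#' report is fully regenerable from (inputs, config, seed).
#'
#' @param cfg an [analysis_config()].
#' @return A `run_report`: `estimates` (results table rows for every
#'   analysis, labelled), `heterogeneity`, `funnel`, `outlier_reports`,
#'   `mediation`, `log`, `seed`, `config_hash`, `version`.
#' @export
run_two_sample_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  exposure <- cfg$exposure
  note("input: %d exposure / %d outcome variants", nrow(exposure),
       nrow(cfg$outcome))
  if (!is.null(cfg$ld)) {
    exposure <- stage("ld_prune",
                      ld_prune(exposure, cfg$ld, cfg$r2_threshold))
    note("ld_prune (r2 <= %g): %d -> %d instruments", cfg$r2_threshold,
         nrow(cfg$exposure), nrow(exposure))
  }
  h <- stage("harmonize",
             harmonize(exposure, cfg$outcome, mediators = cfg$mediators,
                       palindromic_policy = cfg$palindromic_policy))
  note("harmonize: %d shared variants kept", nrow(h))

  ests <- stage("estimators", fit_methods(h, cfg))
  note("estimators: %s", paste(names(ests), collapse = ", "))
  est_tab <- results_table(ests)
  est_tab <- cbind(analysis = "primary", est_tab)

  het <- if (nrow(h) >= 2L) cochran_q(h) else NULL
  funnel <- stage("funnel", funnel_data(h))

  outlier_reports <- list()
  if (!is.null(cfg$q_level) && nrow(h) >= 3L) {
    rep_q <- stage("q_filter",
                   q_contribution_filter(h, cfg$q_level,
                                         estimates_fun = function(hh)
                                           fit_methods(hh, cfg)))
    note("q_filter %s: %d -> %d instruments", cfg$q_level, rep_q$n_before,
         rep_q$n_after)
    outlier_reports[[paste0("q_", cfg$q_level)]] <- rep_q
    t_q <- results_table(rep_q$estimates_after)
    if (nrow(t_q) > 0L) {
      est_tab <- rbind(est_tab,
                       cbind(analysis = paste0("q_filter_", cfg$q_level),
                             t_q))
    }
  }
  if (!is.null(cfg$mediators)) {
    rep_m <- stage("mediator_filter",
                   mediator_exclusion_filter(h, cfg$mediators,
                                             p_threshold = cfg$mediator_p,
                                             estimates_fun = function(hh)
                                               fit_methods(hh, cfg)))
    note("mediator_filter (p < %g): %d -> %d instruments", cfg$mediator_p,
         rep_m$n_before, rep_m$n_after)
    outlier_reports$mediator_exclusion <- rep_m
    t_m <- results_table(rep_m$estimates_after)
    if (nrow(t_m) > 0L) {
      est_tab <- rbind(est_tab,
                       cbind(analysis = "mediator_exclusion", t_m))
    }
  }

  mediation <- list()
  if (length(attr(h, "mediators")) > 0L) {
    total <- ivw(h, "fixed")
    for (lab in attr(h, "mediators")) {
      direct <- stage(paste0("mvmr_", lab), mvmr_ivw(h, mediators = lab))
      mediation[[lab]] <- mediation_decomposition(total, direct)
      note("mvmr[%s]: direct beta %.4f (total %.4f)", lab,
           direct$exposure_beta, total$beta)
      est_tab <- rbind(est_tab,
                       cbind(analysis = paste0("mvmr_", lab),
                             results_table(direct)))
    }
  }

  structure(list(estimates = est_tab, heterogeneity = het,
                 funnel = funnel, outlier_reports = outlier_reports,
                 mediation = mediation, harmonized = h, log = log,
                 seed = cfg$seed,
                 config_hash = fnv1a_hash(cfg),
                 version = as.character(utils::packageVersion("mrpath")),
                 direction = "forward"),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (%s direction), seed %s, config %s\n",
              x$direction, format(x$seed), x$config_hash))
  for (l in x$log) cat(" -", l, "\n")
  print(x$estimates[c("analysis", "method", "n_snps", "beta", "se", "p")])
  invisible(x)
}

#' Render a run report as deterministic text
#'
#' The body contains the log, the estimate table at 12 significant digits,
#' seeds, config hash and package version — no timestamps — so a rerun
#' with identical config and seed is byte-identical.
#'
#' @param report a `run_report`.
#' @return character vector of lines.
#' @export
render_run_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  tab <- report$estimates
  num_cols <- setdiff(names(tab), c("analysis", "method", "n_snps"))
  for (col in num_cols) {
    tab[[col]] <- ifelse(is.na(tab[[col]]), "",
                         formatC(tab[[col]], digits = 12, format = "g"))
  }
  c(sprintf("# mrpath run report v%s", report$version),
    sprintf("# direction: %s", report$direction),
    sprintf("# seed: %s", format(report$seed)),
    sprintf("# config_hash: %s", report$config_hash),
    paste0("# log: ", report$log),
    capture.output(print(tab, row.names = FALSE)))
}

#' Bidirectional (role-swapped) Mendelian randomisation
#'
#' Runs the pipeline in the reverse direction: the outcome trait becomes
#' the exposure, instrumented by its own genome-wide-significant variants
#' (`reverse_exposure`), against the original exposure trait as outcome
#' (`reverse_outcome`). Reusing the forward exposure's instrument set for
#' the reverse exposure is a classic MR mistake and is refused unless
#' `allow_shared_instruments = TRUE`.
#'
#' @param cfg the forward [analysis_config()].
#' @param reverse_exposure [summary_table()] of the outcome trait's own
#'   instruments.
#' @param reverse_outcome [summary_table()] of the original exposure trait
#'   at those variants.
#' @param allow_shared_instruments override the instrument-reuse guard.
#' @param ... overrides passed to the reverse [analysis_config()].
#' @return A `run_report` with `direction = "reverse"`.
#' @export
run_bidirectional <- function(cfg, reverse_exposure, reverse_outcome,
                              allow_shared_instruments = FALSE, ...) {
  stopifnot(inherits(cfg, "analysis_config"),
            inherits(reverse_exposure, "summary_table"),
            inherits(reverse_outcome, "summary_table"))
  shared <- intersect(reverse_exposure$variant_id,
                      cfg$exposure$variant_id)
  if (!allow_shared_instruments &&
      length(shared) == nrow(reverse_exposure)) {
    stop("reverse exposure reuses the forward instrument set; supply the ",
         "reverse trait's own instruments or set ",
         "allow_shared_instruments = TRUE", call. = FALSE)
  }
  rcfg <- analysis_config(exposure = reverse_exposure,
                          outcome = reverse_outcome,
                          ld = cfg$ld, methods = cfg$methods,
                          q_level = cfg$q_level,
                          mediator_p = cfg$mediator_p, phi = cfg$phi,
                          n_boot = cfg$n_boot,
                          r2_threshold = cfg$r2_threshold,
                          palindromic_policy = cfg$palindromic_policy,
                          seed = cfg$seed, ...)
  report <- run_two_sample_pipeline(rcfg)
  report$direction <- "reverse"
  report
}

#' Power of a two-sample MR analysis (non-centrality-parameter approach)
#'
#' For a binary outcome the IVW z statistic has non-centrality parameter
#' `ncp = n_outcome case_fraction (1 - case_fraction) r2_gx log(OR)^2`
#' under the standard logistic-score SE model
#' `se(log OR) = 1/sqrt(2 maf (1-maf) N phi (1-phi))`; power is the
#' upper-tail chi-squared(1, ncp) mass beyond the alpha-level critical
#' value. At `or_alternative = 1` this returns exactly `alpha`.
#'
#' @param n_outcome total outcome-GWAS sample size.
#' @param case_fraction proportion of cases in the outcome GWAS.
#' @param r2_gx variance of the exposure explained by the instruments.
#' @param or_alternative causal odds ratio per 1 SD of exposure under the
#'   alternative.
#' @param alpha significance level (default 0.05).
#' @return power in \[0, 1\] (vectorised over the inputs).
#' @export
mr_power <- function(n_outcome, case_fraction, r2_gx, or_alternative,
                     alpha = 0.05) {
  if (any(r2_gx <= 0) || any(r2_gx >= 1)) {
    stop("r2_gx must lie in (0, 1)", call. = FALSE)
  }
  if (any(case_fraction <= 0) || any(case_fraction >= 1)) {
    stop("case_fraction must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(all(n_outcome > 0), all(or_alternative > 0),
            alpha > 0, alpha < 1)
  ncp <- n_outcome * case_fraction * (1 - case_fraction) * r2_gx *
    log(or_alternative)^2
  pchisq(qchisq(1 - alpha, df = 1), df = 1, ncp = ncp,
         lower.tail = FALSE)
}

benchmark_fit_one <- function(h, method, phi, n_boot, seed) {
  switch(method,
    ivw_fixed = ivw(h, "fixed"),
    ivw_random = ivw(h, "random"),
    ivw_2nd = ivw(h, "second_order"),
    egger = egger_regression(h)$slope,
    weighted_median = weighted_median(h, n_boot = n_boot, seed = seed),
    mbe = mode_based_estimate(h, phi = phi, n_boot = n_boot, seed = seed),
    stop("unknown benchmark method: ", method, call. = FALSE))
}

#' Benchmark the estimator battery over simulation scenarios
#'
#' For each scenario (a [two_sample_config()]) and replicate, simulates a
#' two-sample dataset, fits the requested estimators and aggregates bias,
#' empirical SE, mean reported SE, 95% CI coverage of the true effect and
#' rejection rate of the null, each with its Monte-Carlo SE.
#'
#' @param scenarios named list of [two_sample_config()]s (each config's
#'   own seed is ignored; streams derive from `seed`).
#' @param n_replicates replicates per scenario (>= 100).
#' @param seed master seed.
#' @param methods estimator subset (default: the closed-form ones plus
#'   weighted median and mode).
#' @param phi,n_boot options for the mode/median estimators.
#' @return long data frame: scenario, method, n_replicates, truth, bias,
#'   bias_mc_se, empirical_se, mean_se, coverage, coverage_mc_se,
#'   rejection_rate, rejection_mc_se.
#' @export
run_benchmark <- function(scenarios, n_replicates = 500L, seed,
                          methods = c("ivw_fixed", "ivw_random", "egger",
                                      "weighted_median", "mbe"),
                          phi = 1, n_boot = 200L) {
  if (n_replicates < 100L) {
    stop("n_replicates must be at least 100", call. = FALSE)
  }
  stopifnot(is.list(scenarios), length(scenarios) > 0L)
  if (is.null(names(scenarios))) {
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  }
  rows <- list()
  for (sc_i in seq_along(scenarios)) {
    cfg <- scenarios[[sc_i]]
    stopifnot(inherits(cfg, "two_sample_config"))
    est <- array(NA_real_,
                 dim = c(n_replicates, length(methods), 2L),
                 dimnames = list(NULL, methods, c("beta", "se")))
    for (r in seq_len(n_replicates)) {
      rep_seed <- seed + sc_i * 100000L + r
      cfg$seed <- rep_seed
      sim <- simulate_two_sample(cfg)
      h <- harmonized_from_sim(sim)
      for (m in methods) {
        e <- benchmark_fit_one(h, m, phi, n_boot, rep_seed + 50000L)
        est[r, m, "beta"] <- e$beta
        est[r, m, "se"] <- e$se
      }
    }
    for (m in methods) {
      b <- est[, m, "beta"]
      s <- est[, m, "se"]
      cover <- abs(b - cfg$theta) <= qnorm(0.975) * s
      reject <- abs(b / s) > qnorm(0.975)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = names(scenarios)[sc_i], method = m,
        n_replicates = n_replicates, truth = cfg$theta,
        bias = mean(b) - cfg$theta,
        bias_mc_se = sd(b) / sqrt(n_replicates),
        empirical_se = sd(b), mean_se = mean(s),
        coverage = mean(cover),
        coverage_mc_se = sqrt(mean(cover) * (1 - mean(cover)) /
                                n_replicates),
        rejection_rate = mean(reject),
        rejection_mc_se = sqrt(mean(reject) * (1 - mean(reject)) /
                                 n_replicates),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
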