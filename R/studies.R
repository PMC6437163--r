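# Replication-level studies: the simulation experiments the analysis
# workflow runs (calibration, recovery, pleiotropy robustness, mediation,
# IV-vs-observational contrast, power validation). Each is a pure function
# of its size parameters and seed and returns plain data structures that
# the analysis scripts and the test suite consume directly.

#' Type-I-error calibration of the estimator battery
#'
#' Simulates two-sample datasets under the sharp null (no causal effect, no
#' pleiotropy) and records each estimator's null-rejection indicator at
#' alpha = 0.05 together with Cochran's Q, whose null distribution is
#' chi-squared with J - 1 df.
#'
#' @param n_replicates simulation replicates.
#' @param n_snps instruments per replicate.
#' @param n_boot parametric-bootstrap draws for the median/mode SEs.
#' @param seed master seed.
#' @return list: `rejection` (named rates), `rejection_mc_se`, `q_stats`
#'   (vector of Q values), `q_ks_p` (KS p against chi-squared J-1),
#'   `n_replicates`.
#' @export
calibration_study <- function(n_replicates = 2000L, n_snps = 100L,
                              n_boot = 200L, seed) {
  methods <- c("ivw_fixed", "egger", "weighted_median", "mbe")
  reject <- matrix(NA, n_replicates, length(methods),
                   dimnames = list(NULL, methods))
  qs <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- two_sample_config(n_snps = n_snps, theta = 0,
                             n_exposure = 1e5, n_outcome = 1e5,
                             seed = seed + r)
    h <- harmonized_from_sim(simulate_two_sample(cfg))
    e_ivw <- ivw(h, "fixed")
    qs[r] <- e_ivw$heterogeneity$Q
    reject[r, "ivw_fixed"] <- e_ivw$pvalue < 0.05
    reject[r, "egger"] <- egger_regression(h)$slope$pvalue < 0.05
    reject[r, "weighted_median"] <-
      weighted_median(h, n_boot = n_boot, seed = seed + r)$pvalue < 0.05
    reject[r, "mbe"] <-
      mode_based_estimate(h, n_boot = n_boot,
                          seed = seed + r + 1L)$pvalue < 0.05
  }
  rates <- colMeans(reject)
  list(rejection = rates,
       rejection_mc_se = sqrt(rates * (1 - rates) / n_replicates),
       q_stats = qs,
       q_ks_p = suppressWarnings(
         stats::ks.test(qs, "pchisq", df = n_snps - 1)$p.value),
       n_replicates = n_replicates)
}

#' Effect-recovery study in the tall-exposure / coronary-disease regime
#'
#' Runs the `"height_cad_like"` preset (protective causal log-OR, 828
#' instruments, consortium-scale precisions) across replicates and
#' summarises each estimator's mean estimate and 95% CI coverage of the
#' generating effect.
#'
#' @param n_replicates simulation replicates.
#' @param n_boot bootstrap draws for the median/mode SEs.
#' @param seed master seed.
#' @param theta generating causal effect (default -0.17).
#' @return list: `theta`, `summary` (data frame method, mean_estimate,
#'   bias, coverage, mc_se columns), `n_replicates`.
#' @export
recovery_study <- function(n_replicates = 500L, n_boot = 200L, seed,
                           theta = -0.17) {
  methods <- c("ivw_fixed", "ivw_random", "egger", "weighted_median",
               "mbe")
  est <- array(NA_real_, dim = c(n_replicates, length(methods), 2L),
               dimnames = list(NULL, methods, c("beta", "se")))
  crit <- array(qnorm(0.975), dim = c(length(methods)),
                dimnames = list(methods))
  for (r in seq_len(n_replicates)) {
    cfg <- sim_preset("height_cad_like", seed = seed + r, theta = theta)
    h <- harmonized_from_sim(simulate_two_sample(cfg))
    fits <- list(
      ivw_fixed = ivw(h, "fixed"),
      ivw_random = ivw(h, "random"),
      egger = egger_regression(h)$slope,
      weighted_median = weighted_median(h, n_boot = n_boot,
                                        seed = seed + r),
      mbe = mode_based_estimate(h, n_boot = n_boot, seed = seed + r + 1L))
    for (m in methods) {
      est[r, m, "beta"] <- fits[[m]]$beta
      est[r, m, "se"] <- fits[[m]]$se
      if (m == "egger") crit[m] <- qt(0.975, fits[[m]]$df)
    }
  }
  summ <- do.call(rbind, lapply(methods, function(m) {
    b <- est[, m, "beta"]
    cover <- abs(b - theta) <= crit[[m]] * est[, m, "se"]
    data.frame(method = m, mean_estimate = mean(b),
               bias = mean(b) - theta,
               bias_mc_se = sd(b) / sqrt(n_replicates),
               coverage = mean(cover),
               coverage_mc_se = sqrt(mean(cover) * (1 - mean(cover)) /
                                       n_replicates),
               stringsAsFactors = FALSE)
  }))
  list(theta = theta, summary = summ, n_replicates = n_replicates)
}

#' Robustness ordering under directional pleiotropy (InSIDE satisfied)
#'
#' Plants a directional direct effect in 30% of instruments (drawn
#' independently of instrument strength) and measures each estimator's
#' bias, the rate at which the Egger intercept recovers the sign of the
#' mean direct effect, and the fraction of grossly outlying instruments
#' (per-variant Q above `q_cut`) removed by the L1 per-instrument Q filter.
#'
#' @param n_replicates simulation replicates.
#' @param n_snps instruments per replicate.
#' @param mu_alpha mean planted direct effect (log-OR units).
#' @param sigma_alpha SD of the planted direct effects.
#' @param frac_invalid fraction of instruments carrying the effect.
#' @param theta generating causal effect.
#' @param q_cut per-variant Q defining a "gross outlier" for the removal
#'   metric (default 10).
#' @param seed master seed.
#' @return list: `bias` (named per method), `intercept_sign_rate`,
#'   `outlier_removal_rate` (mean fraction of Q>`q_cut` variants removed
#'   at L1), `n_replicates`.
#' @export
pleiotropy_robustness_study <- function(n_replicates = 500L,
                                        n_snps = 100L, mu_alpha = 0.01,
                                        sigma_alpha = 0.003,
                                        frac_invalid = 0.3,
                                        theta = -0.17, q_cut = 10, seed) {
  methods <- c("ivw_fixed", "egger", "weighted_median")
  est <- matrix(NA_real_, n_replicates, length(methods),
                dimnames = list(NULL, methods))
  sign_ok <- logical(n_replicates)
  removal <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- two_sample_config(
      n_snps = n_snps, theta = theta, n_exposure = 7e5, n_outcome = 1.6e5,
      sigma_gx = sqrt(0.30 / (n_snps * 0.365)),
      pleiotropy = pleiotropy_model("directional", mu = mu_alpha,
                                    sigma = sigma_alpha,
                                    frac_invalid = frac_invalid),
      seed = seed + r)
    sim <- simulate_two_sample(cfg)
    h <- harmonized_from_sim(sim)
    eg <- egger_regression(h)
    est[r, "ivw_fixed"] <- ivw(h, "fixed")$beta
    est[r, "egger"] <- eg$slope$beta
    est[r, "weighted_median"] <-
      weighted_median(h, n_boot = 50L, seed = seed + r)$beta
    sign_ok[r] <- sign(eg$intercept$estimate) == sign(mu_alpha)

    per_q <- cochran_q(h)$per_variant_q
    gross <- names(per_q)[per_q > q_cut]
    if (length(gross) > 0L) {
      filt <- q_contribution_filter(h, "L1")
      removal[r] <- mean(gross %in% filt$excluded$variant_id)
    }
  }
  list(bias = colMeans(est) - theta,
       intercept_sign_rate = mean(sign_ok),
       outlier_removal_rate = mean(removal, na.rm = TRUE),
       n_replicates = n_replicates)
}

#' Mediation studies: direct-effect coverage and attenuation calibration
#'
#' Two designs. (1) Full mediation, two-sample: the exposure affects the
#' outcome only through the mediator; the multivariable-MR direct effect
#' should be null, and its 95% CI should cover zero at the nominal rate.
#' (2) Full mediation, cohort: the three-stage individual-level direct
#' effect should likewise be null. A third arm checks that with a mediator
#' off the causal path the estimated attenuation is near zero.
#'
#' @param n_replicates replicates for each coverage arm.
#' @param n_attenuation replicates for the zero-mediation attenuation arm.
#' @param cohort_n samples per cohort replicate.
#' @param seed master seed.
#' @return list: `mvmr_coverage`, `three_stage_coverage`,
#'   `attenuation_zero_mediation` (mean attenuation %, should be ~0),
#'   MC SEs, `n_replicates`.
#' @export
mediation_study <- function(n_replicates = 500L, n_attenuation = 100L,
                            cohort_n = 4000L, seed) {
  # (1) two-sample multivariable MR under full mediation
  mvmr_cover <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- two_sample_config(
      n_snps = 120L, theta = 0, n_exposure = 3e5, n_outcome = 3e5,
      mediator = list(gamma = 0.4, sigma_m = 0.03, theta_m = 0.3,
                      n_mediator = 3e5),
      seed = seed + r)
    h <- harmonized_from_sim(simulate_two_sample(cfg))
    e <- mvmr_ivw(h)
    mvmr_cover[r] <- e$ci_low <= 0 && 0 <= e$ci_high
  }

  # (2) cohort three-stage direct effect under full mediation
  stage_cover <- logical(n_replicates)
  covs <- c("age", "sex")
  for (r in seq_len(n_replicates)) {
    sc <- simulate_cohort(cohort_sim_config(
      n_samples = cohort_n, theta_exposure = 0, theta_mediator = 0.4,
      gamma_med = 0.4, h2_exposure = 0.3, h2_mediator = 0.15,
      prevalence = 0.15, covariate_effects = FALSE,
      seed = seed + 100000L + r))
    coh <- sc$cohort
    coh$samples$exposure_sd <- residual_inverse_normalise(
      coh, "height", covs)
    coh$samples$mediator_sd <- residual_inverse_normalise(
      coh, "bmi", covs)
    gs_e <- build_genetic_score(
      cohort_table(coh$dosages[, sc$truth$exposure_snps, drop = FALSE],
                   coh$samples),
      weights = sc$truth$beta_exposure_score)
    gs_m <- build_genetic_score(
      cohort_table(coh$dosages[, sc$truth$mediator_snps, drop = FALSE],
                   coh$samples),
      weights = sc$truth$beta_mediator_score)
    m3 <- three_stage_mediation(coh, "cad", "exposure_sd", "mediator_sd",
                                gs_e, gs_m, covs)
    stage_cover[r] <- m3$estimate$ci_low <= 0 && 0 <= m3$estimate$ci_high
  }

  # (3) zero mediation: attenuation percentage should sit at zero
  atten <- numeric(n_attenuation)
  for (r in seq_len(n_attenuation)) {
    cfg <- two_sample_config(
      n_snps = 200L, theta = -0.17, n_exposure = 7e5, n_outcome = 1.6e5,
      sigma_gx = sqrt(0.30 / (200 * 0.365)),
      mediator = list(gamma = 0.3, sigma_m = 0.03, theta_m = 0,
                      n_mediator = 3e5),
      seed = seed + 200000L + r)
    h <- harmonized_from_sim(simulate_two_sample(cfg))
    ms <- mediation_decomposition(ivw(h, "fixed"), mvmr_ivw(h))
    atten[r] <- ms$attenuation_pct
  }

  list(mvmr_coverage = mean(mvmr_cover),
       mvmr_coverage_mc_se = sqrt(mean(mvmr_cover) *
                                    (1 - mean(mvmr_cover)) /
                                    n_replicates),
       three_stage_coverage = mean(stage_cover),
       three_stage_coverage_mc_se = sqrt(mean(stage_cover) *
                                           (1 - mean(stage_cover)) /
                                           n_replicates),
       attenuation_zero_mediation = mean(atten),
       attenuation_mc_se = sd(atten) / sqrt(n_attenuation),
       n_replicates = n_replicates)
}

#' Instrumental-variable vs observational contrast under confounding
#'
#' Large confounded cohorts: an unmeasured confounder raises both the
#' exposure and the outcome risk, so the conventional logistic regression
#' is biased while the genetic-score two-stage (control-function) estimate
#' recovers the generating conditional log-OR. A small number of cohort
#' replicates are averaged so the comparison measures the estimators, not
#' a single noise draw; the residual relative error of the IV mean
#' reflects logistic non-collapsibility (the confounder share not captured
#' by the first-stage residual), a few percent toward the null.
#'
#' @param n_samples cohort size per replicate.
#' @param n_replicates cohort replicates averaged (default 16).
#' @param theta generating conditional log-OR per SD of exposure.
#' @param seed RNG seed.
#' @return list: `iv_estimate`/`observational_estimate` (means across
#'   replicates) with `iv_mc_se`/`observational_mc_se`, `theta`,
#'   `relative_error_iv`, `observational_bias_z` (bias of the mean in
#'   units of its MC SE), `f_stage1` (mean), `per_replicate` data frame.
#' @export
iv_vs_observational_study <- function(n_samples = 50000L,
                                      n_replicates = 16L,
                                      theta = log(0.77), seed) {
  per <- data.frame(iv = numeric(n_replicates),
                    iv_se = numeric(n_replicates),
                    obs = numeric(n_replicates),
                    obs_se = numeric(n_replicates),
                    f1 = numeric(n_replicates))
  covs <- c("age", "sex")
  for (r in seq_len(n_replicates)) {
    sc <- simulate_cohort(cohort_sim_config(
      n_samples = n_samples, theta_exposure = theta, theta_mediator = 0,
      gamma_med = 0, h2_exposure = 0.3,
      confounder_exposure = 0.4, confounder_outcome = 0.5,
      prevalence = 0.1, seed = seed + r))
    coh <- sc$cohort
    coh$samples$exposure_sd <- residual_inverse_normalise(
      coh, "height", c(covs, "batch"))
    gs <- build_genetic_score(
      cohort_table(coh$dosages[, sc$truth$exposure_snps, drop = FALSE],
                   coh$samples),
      weights = sc$truth$beta_exposure_score)
    iv <- two_stage_iv(coh, "cad", "exposure_sd", gs, covs,
                       variant = "control_function", n_boot = 0L)
    obs <- observational_association(coh, "cad", "exposure_sd", covs)
    per$iv[r] <- iv$estimate$beta
    per$iv_se[r] <- iv$estimate$se
    per$obs[r] <- obs$log_or
    per$obs_se[r] <- obs$log_or_se
    per$f1[r] <- iv$f_stage1
  }
  iv_mean <- mean(per$iv)
  obs_mean <- mean(per$obs)
  obs_mc_se <- sd(per$obs) / sqrt(n_replicates)
  list(iv_estimate = iv_mean,
       iv_mc_se = sd(per$iv) / sqrt(n_replicates),
       observational_estimate = obs_mean,
       observational_mc_se = obs_mc_se,
       theta = theta,
       relative_error_iv = abs(iv_mean - theta) / abs(theta),
       observational_bias_z = (obs_mean - theta) / obs_mc_se,
       f_stage1 = mean(per$f1),
       per_replicate = per)
}

#' Validate the analytic power formula against simulated rejection rates
#'
#' For each odds ratio on the grid, simulates two-sample datasets whose
#' outcome GWAS size is the case-control-scaled `n_outcome
#' case_fraction (1 - case_fraction)` implied by the power model, runs
#' fixed-effect IVW and compares the empirical rejection rate at
#' alpha = 0.05 with [mr_power()].
#'
#' @param or_grid odds ratios under the alternative.
#' @param n_outcome,case_fraction outcome GWAS design.
#' @param r2_gx target instrument strength.
#' @param n_snps instruments.
#' @param n_replicates replicates per grid point.
#' @param seed master seed.
#' @return data frame: or, analytic_power, empirical_rejection, mc_se,
#'   abs_error.
#' @export
power_validation_study <- function(or_grid = c(1.03, 1.05, 1.08),
                                   n_outcome = 5e4, case_fraction = 0.5,
                                   r2_gx = 0.05, n_snps = 50L,
                                   n_replicates = 2000L, seed) {
  n_eff <- n_outcome * case_fraction * (1 - case_fraction)
  # the formula computes power at a fixed instrument R^2, so the oracle
  # holds R^2 fixed too: equal effects at a single allele frequency
  maf <- 0.3
  bx_fixed <- rep(sqrt(r2_gx / (n_snps * 2 * maf * (1 - maf))), n_snps)
  rows <- lapply(seq_along(or_grid), function(k) {
    or <- or_grid[k]
    rej <- vapply(seq_len(n_replicates), function(r) {
      cfg <- two_sample_config(n_snps = n_snps, beta_gx = bx_fixed,
                               maf_range = c(maf, maf),
                               theta = log(or), n_exposure = 5e5,
                               n_outcome = n_eff,
                               seed = seed + k * 100000L + r)
      ivw(harmonized_from_sim(simulate_two_sample(cfg)),
          "fixed")$pvalue < 0.05
    }, NA)
    emp <- mean(rej)
    data.frame(or = or,
               analytic_power = mr_power(n_outcome, case_fraction,
                                         r2_gx, or),
               empirical_rejection = emp,
               mc_se = sqrt(emp * (1 - emp) / n_replicates),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$abs_error <- abs(out$analytic_power - out$empirical_rejection)
  out
}
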