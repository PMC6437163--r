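# Cohort QC, phenotype preprocessing, genetic scores, observational and
# two-/three-stage IV estimators.

small_cohort <- function(seed = 1L, n = 600L, ...) {
  simulate_cohort(cohort_sim_config(n_samples = n, seed = seed, ...))
}

test_that("QC removes related samples, height outliers and low-INFO
          variants, and is the identity on clean data", {
  sc <- small_cohort(seed = 2L)
  clean <- qc_filter(sc$cohort)
  expect_equal(nrow(clean$dosages), nrow(sc$cohort$dosages))
  expect_equal(unname(attr(clean, "exclusion_log")),
               c(0L, 0L, 0L))

  dirty <- sc$cohort
  dirty$samples$height[1L] <- mean(dirty$samples$height) +
    8 * sd(dirty$samples$height)           # > 5 SD away
  dirty$samples$kinship <- 0
  dirty$samples$kinship[2:3] <- 0.25       # related pair
  dirty$info[5L] <- 0.39                   # below the 0.4 INFO cutoff
  filt <- qc_filter(dirty)
  log <- attr(filt, "exclusion_log")
  expect_equal(unname(log["height_outlier"]), 1L)
  expect_equal(unname(log["related"]), 2L)
  expect_equal(unname(log["low_info_variant"]), 1L)
  expect_equal(nrow(filt$dosages), nrow(dirty$dosages) - 3L)
  expect_equal(ncol(filt$dosages), ncol(dirty$dosages) - 1L)
  expect_false("ex005" %in% colnames(filt$dosages))

  # removing every sample is an error
  all_related <- sc$cohort
  all_related$samples$kinship <- 1
  expect_error(qc_filter(all_related), "every sample")
})

test_that("residual inverse-normalisation yields a standard-normal column,
          preserves ranks, and is invariant to monotone transforms", {
  sc <- small_cohort(seed = 3L, n = 10000L)
  covs <- c("age", "sex", "pc1", "pc2", "pc3", "pc4", "pc5", "batch")
  z <- residual_inverse_normalise(sc$cohort, "height", covs)
  expect_lt(abs(mean(z)), 1e-6)
  expect_equal(sd(z), 1, tolerance = 1e-3)

  # with no real covariate signal the transform preserves ranks
  coh2 <- sc$cohort
  coh2$samples$noise_pheno <- rnorm(10000L)
  z2 <- residual_inverse_normalise(coh2, "noise_pheno", c("pc1", "pc2"))
  expect_gt(cor(z2, coh2$samples$noise_pheno, method = "spearman"), 0.999)

  # strictly monotone transform of the phenotype (no covariate signal):
  # near-identical output because only the ranks matter
  coh3 <- coh2
  coh3$samples$mono <- exp(coh2$samples$noise_pheno / 3)
  z_id <- residual_inverse_normalise(coh3, "mono", "pc1")
  z_raw <- residual_inverse_normalise(coh3, "noise_pheno", "pc1")
  expect_gt(cor(z_id, z_raw), 0.999)

  # ties get average ranks and stay finite
  coh4 <- sc$cohort
  coh4$samples$tied <- rep(c(1, 2, 2, 3), length.out = 10000L)
  z4 <- residual_inverse_normalise(coh4, "tied", "sex")
  expect_true(all(is.finite(z4)))

  expect_error(residual_inverse_normalise(coh4, "nope", "age"),
               "not found")
  coh4$samples$const <- 1
  expect_error(residual_inverse_normalise(coh4, "const", "age"),
               "constant")
})

test_that("genetic scores sum oriented dosages, rescale weighted scores to
          the unweighted range, and mean-impute missing dosages", {
  d <- matrix(c(2, 1, 0, 1, 0, 2), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("v1", "v2", "v3")))
  coh <- cohort_table(d, data.frame(sample_id = c("a", "b"),
                                    height = c(170, 180)))
  un <- build_genetic_score(coh)
  expect_equal(un$values, c(3, 3))
  expect_equal(un$kind, "unweighted")

  # equal weights reproduce the unweighted score exactly
  wt <- build_genetic_score(coh, weights = c(v1 = 0.3, v2 = 0.3, v3 = 0.3))
  expect_equal(wt$values, un$values)
  expect_equal(wt$rescale_factor, 0.3)

  # mismatched weight set is an input error
  expect_error(build_genetic_score(coh, weights = c(v1 = 1, v2 = 1)),
               "match")

  # missing dosage is imputed at 2 EAF
  d_na <- d
  d_na[1L, 2L] <- NA
  coh_na <- cohort_table(d_na, coh$samples, eaf = c(0.5, 0.25, 0.5))
  sc_na <- build_genetic_score(coh_na)
  expect_equal(sc_na$values[1L], 2 + 2 * 0.25 + 0)
  expect_equal(sc_na$imputed, 1L)

  # simulated cohort: score-exposure R2 matches the generative heritability
  big <- simulate_cohort(cohort_sim_config(n_samples = 20000L,
                                           h2_exposure = 0.3, seed = 9L))
  covs <- c("age", "sex", "pc1", "pc2", "pc3", "pc4", "pc5", "batch")
  z <- residual_inverse_normalise(big$cohort, "height", covs)
  w_true <- big$truth$beta_exposure_score
  coh_ex <- cohort_table(big$cohort$dosages[, names(w_true)],
                         big$cohort$samples)
  gs <- build_genetic_score(coh_ex, weights = w_true)
  r2 <- summary(lm(z ~ gs$values))$r.squared
  expect_gt(r2, 0.27)
  expect_lt(r2, 0.33)
})

test_that("observational regression reports the OR per SD and guards
          degenerate input", {
  sc <- simulate_cohort(cohort_sim_config(n_samples = 20000L,
                                          theta_exposure = -0.2,
                                          h2_exposure = 0.3,
                                          prevalence = 0.15, seed = 11L))
  coh <- sc$cohort
  coh$samples$height_sd <- residual_inverse_normalise(
    coh, "height", c("age", "sex", "batch"))
  obs <- observational_association(coh, "cad", "height_sd",
                                   c("age", "sex"))
  # no confounding in this configuration: estimate near the generating
  # conditional log-OR
  expect_lt(abs(obs$log_or - (-0.2)), 3.5 * obs$log_or_se + 0.02)
  expect_equal(obs$or, exp(obs$log_or))

  coh$samples$flat <- 1
  expect_error(observational_association(coh, "cad", "flat", "age"),
               "constant")
})

test_that("two-stage IV variants agree without confounding and the weak
          instrument guard fires", {
  sc <- simulate_cohort(cohort_sim_config(n_samples = 15000L,
                                          theta_exposure = -0.25,
                                          h2_exposure = 0.3,
                                          prevalence = 0.2, seed = 13L))
  coh <- sc$cohort
  coh$samples$height_sd <- residual_inverse_normalise(
    coh, "height", c("age", "sex", "batch"))
  gs <- build_genetic_score(
    cohort_table(coh$dosages[, sc$truth$exposure_snps], coh$samples),
    weights = sc$truth$beta_exposure_score)

  cf <- two_stage_iv(coh, "cad", "height_sd", gs, c("age", "sex"),
                     variant = "control_function", n_boot = 50L,
                     seed = 21L)
  su <- two_stage_iv(coh, "cad", "height_sd", gs, c("age", "sex"),
                     variant = "substitution", n_boot = 0L)
  expect_gt(cf$f_stage1, 100)
  expect_lt(abs(cf$estimate$beta - su$estimate$beta),
            2 * cf$estimate$se)
  expect_lt(abs(cf$estimate$beta - (-0.25)), 3 * cf$estimate$se + 0.03)
  # stage-1 linear identity: fitted + residuals reproduce the response
  expect_equal(cf$stage1$fitted + cf$stage1$residuals,
               coh$samples$height_sd, tolerance = 1e-9,
               ignore_attr = TRUE)

  # a score unrelated to the exposure triggers the weak-instrument warning
  coh$samples$junk_score <- rnorm(nrow(coh$samples))
  expect_warning(two_stage_iv(coh, "cad", "height_sd",
                              coh$samples$junk_score, c("age", "sex"),
                              n_boot = 0L),
                 "weak instrument")

  # point estimate is invariant to adding a covariate orthogonal to
  # score, exposure and outcome
  coh$samples$orth <- rnorm(nrow(coh$samples))
  su2 <- two_stage_iv(coh, "cad", "height_sd", gs,
                      c("age", "sex", "orth"), variant = "substitution",
                      n_boot = 0L)
  expect_lt(abs(su2$estimate$beta - su$estimate$beta), 0.02)
})

test_that("three-stage mediation recovers the direct effect and guards
          collinear scores", {
  # mediator with zero effect on the outcome: direct effect matches the
  # plain two-stage estimate
  sc <- simulate_cohort(cohort_sim_config(n_samples = 15000L,
                                          theta_exposure = -0.25,
                                          theta_mediator = 0,
                                          gamma_med = 0.4,
                                          h2_exposure = 0.3,
                                          h2_mediator = 0.15,
                                          prevalence = 0.2, seed = 17L))
  coh <- sc$cohort
  covs <- c("age", "sex")
  coh$samples$height_sd <- residual_inverse_normalise(
    coh, "height", c("age", "sex", "batch"))
  coh$samples$bmi_sd <- residual_inverse_normalise(
    coh, "bmi", c("age", "sex", "batch"))
  gs_e <- build_genetic_score(
    cohort_table(coh$dosages[, sc$truth$exposure_snps], coh$samples),
    weights = sc$truth$beta_exposure_score)
  gs_m <- build_genetic_score(
    cohort_table(coh$dosages[, sc$truth$mediator_snps], coh$samples),
    weights = sc$truth$beta_mediator_score)

  ts <- two_stage_iv(coh, "cad", "height_sd", gs_e, covs, n_boot = 0L)
  m3 <- three_stage_mediation(coh, "cad", "height_sd", "bmi_sd",
                              gs_e, gs_m, covs)
  expect_lt(abs(m3$estimate$beta - ts$estimate$beta),
            2.5 * m3$estimate$se)

  # reusing the exposure score as mediator score is refused
  expect_error(
    suppressWarnings(three_stage_mediation(coh, "cad", "height_sd",
                                           "bmi_sd", gs_e, gs_e, covs)),
    "collinear")
})
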