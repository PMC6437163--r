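# Synthetic-data generators with known causal structure: two-sample GWAS
# summary statistics with configurable horizontal pleiotropy, individual-
# level cohorts with confounding and mediation, and block LD structure.
# Every generator is a pure function of (config, seed).

#' Pleiotropy model for the two-sample generator
#'
#' `none`: all instruments valid. `balanced`: per-variant direct effects
#' `alpha_j ~ N(0, sigma)`. `directional`: `alpha_j ~ N(mu, sigma)`
#' (InSIDE holds: alpha independent of instrument strength).
#' `inside_violating`: `alpha_j = delta beta_gx_j + N(0, sigma)`, coupling
#' the direct effect to instrument strength.
#'
#' @param type one of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param mu mean direct effect (directional model).
#' @param sigma SD of the direct effects.
#' @param delta coupling to instrument strength (inside_violating model).
#' @param frac_invalid fraction of instruments carrying a direct effect
#'   (default 1; e.g. 0.3 plants pleiotropy in 30% of instruments).
#' @return list describing the model.
#' @export
pleiotropy_model <- function(type = c("none", "balanced", "directional",
                                      "inside_violating"),
                             mu = 0, sigma = 0, delta = 0,
                             frac_invalid = 1) {
  type <- match.arg(type)
  stopifnot(sigma >= 0, frac_invalid >= 0, frac_invalid <= 1)
  list(type = type, mu = mu, sigma = sigma, delta = delta,
       frac_invalid = frac_invalid)
}

#' Configuration for the two-sample summary-statistic generator
#'
#' Defaults describe a generic well-powered two-sample design; the
#' `"height_cad_like"` preset of [sim_preset()] mirrors the
#' height-to-coronary-disease regime (828 instruments explaining ~30% of
#' the exposure, exposure GWAS of 700,000, case-control-scaled outcome
#' GWAS, protective causal log-OR -0.17).
#'
#' @param n_snps number of instruments.
#' @param sigma_gx SD of the true per-allele exposure effects (SD units);
#'   alternatively supply `beta_gx` as a fixed vector.
#' @param beta_gx optional fixed vector of true exposure effects.
#' @param maf_range uniform range for minor-allele frequencies, within
#'   (0, 0.5].
#' @param n_exposure,n_outcome GWAS sample sizes driving the summary-SE
#'   model `se = 1/sqrt(2 maf (1-maf) n)`; for a binary outcome use the
#'   effective (case-control-scaled) size `N phi (1-phi)` on the log-OR
#'   scale.
#' @param theta true causal effect of the exposure on the outcome (log-OR
#'   per 1 SD).
#' @param pleiotropy a [pleiotropy_model()].
#' @param mediator optional list describing a mediator GWAS:
#'   `gamma` (exposure effect on mediator), `sigma_m` (SD of the
#'   mediator's own genetic effects), `theta_m` (mediator effect on
#'   outcome; the outcome model becomes
#'   `by = theta bx + theta_m bm + alpha`), `n_mediator` (its GWAS size).
#' @param seed RNG seed (required).
#' @return A `two_sample_config` list.
#' @export
two_sample_config <- function(n_snps = 100L, sigma_gx = 0.05,
                              beta_gx = NULL, maf_range = c(0.05, 0.5),
                              n_exposure = 1e5, n_outcome = 1e5,
                              theta = 0,
                              pleiotropy = pleiotropy_model("none"),
                              mediator = NULL, seed) {
  stopifnot(n_snps >= 1L, sigma_gx >= 0, n_exposure > 0, n_outcome > 0,
            length(maf_range) == 2L, maf_range[1L] > 0,
            maf_range[2L] <= 0.5, maf_range[1L] <= maf_range[2L])
  if (!is.null(beta_gx)) stopifnot(length(beta_gx) == n_snps)
  if (!is.null(mediator)) {
    mediator <- utils::modifyList(list(gamma = 0, sigma_m = 0.05,
                                       theta_m = 0, n_mediator = 1e5),
                                  mediator)
  }
  structure(list(n_snps = as.integer(n_snps), sigma_gx = sigma_gx,
                 beta_gx = beta_gx, maf_range = maf_range,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 theta = theta, pleiotropy = pleiotropy,
                 mediator = mediator, seed = seed),
            class = "two_sample_config")
}

#' Named parameter presets for regime-realistic simulations
#'
#' `"height_cad_like"`: J = 828 instruments, exposure GWAS of 700,000,
#' effective outcome GWAS size 160,000 (case-control scaled), true
#' causal log-OR -0.17 per SD, sigma_gx calibrated so the instruments
#' explain ~30% of exposure variance. All values are preset labels
#' describing a regime, not claims about any dataset.
#'
#' @param name preset name.
#' @param seed RNG seed (required).
#' @param ... overrides passed to [two_sample_config()].
#' @return A `two_sample_config`.
#' @export
sim_preset <- function(name = c("height_cad_like"), seed, ...) {
  name <- match.arg(name)
  # E[2 maf (1-maf)] for maf ~ U(0.05, 0.5) is ~0.365, so
  # sigma_gx = sqrt(0.30 / (828 * 0.365)) gives ~30% explained variance
  base <- list(n_snps = 828L, sigma_gx = sqrt(0.30 / (828 * 0.365)),
               n_exposure = 7e5, n_outcome = 1.6e5, theta = -0.17,
               maf_range = c(0.05, 0.5))
  args <- utils::modifyList(base, list(...))
  args$seed <- seed
  do.call(two_sample_config, args)
}

# per-variant GWAS standard error under the standardized-trait model
gwas_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

truth_object <- function(cfg, extra) {
  structure(c(list(config = cfg), extra), class = "simulation_truth")
}

make_summary_table <- function(ids, beta, se, maf, n, label, type) {
  summary_table(data.frame(variant_id = ids,
                           effect_allele = "A", other_allele = "G",
                           eaf = maf, beta = beta, se = se,
                           pvalue = pmax(2 * pnorm(-abs(beta / se)),
                                         .Machine$double.xmin),
                           n = n, stringsAsFactors = FALSE),
                trait_label = label, trait_type = type)
}

#' Simulate a two-sample MR dataset
#'
#' Per variant: a true exposure effect is drawn half-normal (effects are
#' reported for the exposure-increasing allele; or taken from the config),
#' a direct (pleiotropic) outcome effect per the pleiotropy model, and the
#' true outcome effect `theta beta_gx + alpha` (plus
#' `theta_m beta_gm` when a mediator is configured, with
#' `beta_gm = gamma beta_gx + own effects`). Observed effects add
#' independent normal noise with `se = 1/sqrt(2 maf (1-maf) n)` on each
#' side — the no-sample-overlap property of a two-sample design. Binary
#' outcome effects are produced on the log-OR scale directly.
#'
#' @param cfg a [two_sample_config()].
#' @param ld optional [ld_info()] in matrix form covering `n_snps`
#'   variants (e.g. from [simulate_ld_blocks()]); summary noise is then
#'   drawn with that correlation within each sample.
#' @return list with `exposure`, `outcome` (and `mediator`)
#'   [summary_table()]s and `truth` (a `simulation_truth` holding the
#'   generating parameters, the per-variant pleiotropic effects and the
#'   realized instrument R²).
#' @export
simulate_two_sample <- function(cfg, ld = NULL) {
  stopifnot(inherits(cfg, "two_sample_config"))
  with_seed(cfg$seed, {
    J <- cfg$n_snps
    ids <- sprintf("rs%05d", seq_len(J))
    maf <- runif(J, cfg$maf_range[1L], cfg$maf_range[2L])
    # true effects are reported for the exposure-increasing allele, so they
    # are non-negative (half-normal with scale sigma_gx; E[bx^2] = sigma^2,
    # which is what the R^2 calibration uses); a fixed beta_gx vector is
    # taken as supplied. This keeps "directional" pleiotropy directional
    # after orientation: re-orienting a variant flips its direct effect too.
    bx_true <- cfg$beta_gx %||% abs(rnorm(J, 0, cfg$sigma_gx))

    pl <- cfg$pleiotropy
    alpha <- numeric(J)
    invalid <- rep(FALSE, J)
    if (pl$type != "none") {
      n_invalid <- round(pl$frac_invalid * J)
      invalid[sample.int(J, n_invalid)] <- TRUE
      alpha[invalid] <- switch(pl$type,
        balanced = rnorm(n_invalid, 0, pl$sigma),
        directional = rnorm(n_invalid, pl$mu, pl$sigma),
        inside_violating = pl$delta * bx_true[invalid] +
          rnorm(n_invalid, 0, pl$sigma))
    }

    bm_true <- NULL
    by_true <- cfg$theta * bx_true + alpha
    if (!is.null(cfg$mediator)) {
      med <- cfg$mediator
      bm_true <- med$gamma * bx_true + rnorm(J, 0, med$sigma_m)
      by_true <- by_true + med$theta_m * bm_true
    }

    se_x <- gwas_se(maf, cfg$n_exposure)
    se_y <- gwas_se(maf, cfg$n_outcome)
    draw_noise <- function(se) {
      z <- rnorm(J)
      if (!is.null(ld)) {
        rho <- ld_cor_matrix(ld, ids)
        z <- as.numeric(crossprod(chol(rho), z))
      }
      z * se
    }
    bx_obs <- bx_true + draw_noise(se_x)
    by_obs <- by_true + draw_noise(se_y)

    exposure <- make_summary_table(ids, bx_obs, se_x, maf,
                                   cfg$n_exposure, "exposure",
                                   "quantitative")
    outcome <- make_summary_table(ids, by_obs, se_y, maf,
                                  cfg$n_outcome, "outcome", "binary")
    mediator <- NULL
    if (!is.null(bm_true)) {
      se_m <- gwas_se(maf, cfg$mediator$n_mediator)
      mediator <- make_summary_table(ids, bm_true + draw_noise(se_m),
                                     se_m, maf, cfg$mediator$n_mediator,
                                     "mediator", "quantitative")
    }
    truth <- truth_object(cfg, list(
      variant_id = ids, maf = maf, beta_gx_true = bx_true,
      beta_gm_true = bm_true, alpha = alpha, invalid = invalid,
      r2_instruments = sum(2 * maf * (1 - maf) * bx_true^2)))
    list(exposure = exposure, outcome = outcome, mediator = mediator,
         truth = truth)
  })
}

# Build the harmonized set directly from a simulation (the generator emits
# pre-aligned tables, so this equals harmonize() on them; asserted in the
# test suite and used on hot simulation loops).
harmonized_from_sim <- function(sim) {
  h <- data.frame(variant_id = sim$exposure$variant_id,
                  beta_gx = sim$exposure$beta, se_gx = sim$exposure$se,
                  beta_gy = sim$outcome$beta, se_gy = sim$outcome$se,
                  stringsAsFactors = FALSE)
  med_labels <- character(0)
  if (!is.null(sim$mediator)) {
    h$beta_gm_mediator <- sim$mediator$beta
    h$se_gm_mediator <- sim$mediator$se
    med_labels <- "mediator"
  }
  neg <- h$beta_gx < 0
  flip_cols <- grep("^beta_", names(h), value = TRUE)
  h[neg, flip_cols] <- -h[neg, flip_cols]
  structure(h,
            orientation_log = data.frame(
              variant_id = h$variant_id,
              action = ifelse(neg, "flipped", "kept"),
              reason = ifelse(neg, "oriented_to_increasing", "kept"),
              stringsAsFactors = FALSE),
            outcome_type = "binary",
            exposure_label = "exposure", outcome_label = "outcome",
            mediators = med_labels,
            instrument_hash = fnv1a_hash(sort(h$variant_id)),
            class = c("harmonized_set", "data.frame"))
}

#' Configuration for the individual-level cohort generator
#'
#' The causal diagram is exposure -> mediator -> binary outcome with a
#' shared normal confounder: genotype scores instrument the exposure and
#' the mediator separately, the exposure is standardized to SD 1 with
#' heritability `h2_exposure` via its score, the mediator is
#' `gamma_med exposure + own genetics + confounder + noise` (SD 1), and
#' the outcome is Bernoulli with logit
#' `intercept + theta_exposure exposure + theta_mediator mediator +
#' confounder_outcome U`, the intercept solved by bisection for the target
#' prevalence.
#'
#' @param n_samples cohort size.
#' @param n_snps_exposure_score,n_snps_mediator_score variants per score.
#' @param h2_exposure variance of the exposure explained by its score, in
#'   \[0, 1).
#' @param h2_mediator variance of the mediator explained by its own score.
#' @param gamma_med effect of exposure on mediator (SD units).
#' @param confounder_exposure,confounder_mediator,confounder_outcome
#'   effects of the standard-normal confounder.
#' @param theta_exposure,theta_mediator log-OR effects on the outcome.
#' @param prevalence target outcome prevalence in (0, 1).
#' @param maf_range uniform MAF range for score variants.
#' @param covariate_effects logical: give age/sex small effects on the
#'   observable height phenotype (exercises residualisation).
#' @param seed RNG seed (required).
#' @return A `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_samples = 10000L,
                              n_snps_exposure_score = 60L,
                              n_snps_mediator_score = 60L,
                              h2_exposure = 0.3, h2_mediator = 0.15,
                              gamma_med = 0,
                              confounder_exposure = 0,
                              confounder_mediator = 0,
                              confounder_outcome = 0,
                              theta_exposure = 0, theta_mediator = 0,
                              prevalence = 0.1,
                              maf_range = c(0.1, 0.4),
                              covariate_effects = TRUE, seed) {
  stopifnot(n_samples >= 10L, h2_exposure >= 0, h2_exposure < 1,
            h2_mediator >= 0, h2_mediator < 1,
            prevalence > 0, prevalence < 1)
  resid_e <- 1 - h2_exposure - confounder_exposure^2
  if (resid_e <= 0) {
    stop("h2_exposure + confounder_exposure^2 must be < 1", call. = FALSE)
  }
  var_from_exposure <- gamma_med^2 +
    2 * gamma_med * confounder_mediator * confounder_exposure
  resid_m <- 1 - var_from_exposure - h2_mediator - confounder_mediator^2
  if (resid_m <= 0) {
    stop("mediator variance budget exceeded (gamma_med / h2_mediator / ",
         "confounder_mediator too large)", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_snps_exposure_score = as.integer(n_snps_exposure_score),
                 n_snps_mediator_score = as.integer(n_snps_mediator_score),
                 h2_exposure = h2_exposure, h2_mediator = h2_mediator,
                 gamma_med = gamma_med,
                 confounder_exposure = confounder_exposure,
                 confounder_mediator = confounder_mediator,
                 confounder_outcome = confounder_outcome,
                 theta_exposure = theta_exposure,
                 theta_mediator = theta_mediator,
                 prevalence = prevalence, maf_range = maf_range,
                 covariate_effects = covariate_effects, seed = seed,
                 resid_e = resid_e, resid_m = resid_m),
            class = "cohort_sim_config")
}

# genotype matrix and a score with variance exactly target_var in
# expectation: effects ~ N(0, 1) rescaled
score_component <- function(n, J, maf_range, target_var, prefix) {
  maf <- runif(J, maf_range[1L], maf_range[2L])
  G <- matrix(rbinom(n * J, 2L, rep(maf, each = n)), n, J)
  colnames(G) <- sprintf("%s%03d", prefix, seq_len(J))
  b <- rnorm(J)
  vg <- sum(2 * maf * (1 - maf) * b^2)
  b <- b * sqrt(target_var / vg)
  list(G = G, maf = maf, beta = b,
       g = as.numeric(G %*% b) - sum(2 * maf * b))
}

#' Simulate an individual-level cohort with known causal structure
#'
#' @param cfg a [cohort_sim_config()].
#' @return list with `cohort` (a [cohort_table()] whose samples carry
#'   `height` (cm), `bmi`, binary `cad`, covariates `age`, `sex`,
#'   `pc1..pc5`, `batch`) and `truth` (a `simulation_truth` with the score
#'   effects, realized R² and the solved intercept).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_samples
    U <- rnorm(n)
    ce <- score_component(n, cfg$n_snps_exposure_score, cfg$maf_range,
                          cfg$h2_exposure, "ex")
    cm <- score_component(n, cfg$n_snps_mediator_score, cfg$maf_range,
                          cfg$h2_mediator, "md")
    exposure <- ce$g + cfg$confounder_exposure * U +
      rnorm(n, 0, sqrt(cfg$resid_e))
    mediator <- cfg$gamma_med * exposure + cm$g +
      cfg$confounder_mediator * U + rnorm(n, 0, sqrt(cfg$resid_m))

    lin <- cfg$theta_exposure * exposure +
      cfg$theta_mediator * mediator + cfg$confounder_outcome * U
    # intercept for the target prevalence, bisection to 1e-4
    lo <- -30
    hi <- 30
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      K <- mean(plogis(mid + lin))
      if (abs(K - cfg$prevalence) < 1e-4) break
      if (K > cfg$prevalence) hi <- mid else lo <- mid
    }
    intercept <- mid
    outcome <- rbinom(n, 1L, plogis(intercept + lin))

    age <- runif(n, 40, 70)
    sex <- rbinom(n, 1L, 0.5)
    pcs <- matrix(rnorm(n * 5L), n, 5L,
                  dimnames = list(NULL, paste0("pc", 1:5)))
    batch <- factor(sample.int(5L, n, replace = TRUE))
    height <- 168.5 + 6.5 * exposure
    bmi <- 27 + 4.7 * mediator
    if (cfg$covariate_effects) {
      height <- height + 0.03 * (age - 55) + 0.5 * sex
      bmi <- bmi + 0.02 * (age - 55)
    }
    samples <- data.frame(sample_id = sprintf("S%06d", seq_len(n)),
                          age = age, sex = sex, pcs, batch = batch,
                          height = height, bmi = bmi, cad = outcome,
                          stringsAsFactors = FALSE)
    G <- cbind(ce$G, cm$G)
    truth <- truth_object(cfg, list(
      exposure_snps = colnames(ce$G), mediator_snps = colnames(cm$G),
      beta_exposure_score = setNames(ce$beta, colnames(ce$G)),
      beta_mediator_score = setNames(cm$beta, colnames(cm$G)),
      maf = setNames(c(ce$maf, cm$maf), colnames(G)),
      intercept = intercept,
      realized_r2_exposure = var(ce$g) / var(exposure),
      latent_exposure_sd = sd(exposure),
      expected_attenuation_pct =
        if (cfg$theta_exposure + cfg$theta_mediator * cfg$gamma_med != 0) {
          100 * cfg$theta_mediator * cfg$gamma_med /
            (cfg$theta_exposure + cfg$theta_mediator * cfg$gamma_med)
        } else NA_real_))
    list(cohort = cohort_table(G, samples,
                               info = rep(1, ncol(G)),
                               eaf = setNames(c(ce$maf, cm$maf),
                                              colnames(G))),
         truth = truth)
  })
}

#' Block-exchangeable LD structure
#'
#' Builds a block-diagonal correlation matrix with `n_blocks` blocks of
#' `block_size` variants and within-block correlation `rho`. The ids match
#' the two-sample generator's (`rs00001`, ...), so the result can be passed
#' straight to [simulate_two_sample()] (correlated summary noise) and
#' [ivw_correlated()].
#'
#' @param n_blocks,block_size block layout.
#' @param rho within-block correlation, |rho| < 1 and above the
#'   exchangeable positive-definiteness bound `-1/(block_size - 1)`.
#' @param ids optional variant ids (default `rs00001...`).
#' @return An [ld_info()] in matrix form.
#' @export
simulate_ld_blocks <- function(n_blocks, block_size, rho, ids = NULL) {
  if (abs(rho) >= 1 ||
      (block_size > 1 && rho <= -1 / (block_size - 1))) {
    stop("rho = ", rho, " does not give a positive-definite ",
         "exchangeable block of size ", block_size, call. = FALSE)
  }
  J <- n_blocks * block_size
  ids <- ids %||% sprintf("rs%05d", seq_len(J))
  stopifnot(length(ids) == J)
  block <- matrix(rho, block_size, block_size)
  diag(block) <- 1
  m <- matrix(0, J, J, dimnames = list(ids, ids))
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block_size + 1L):(b * block_size)
    m[idx, idx] <- block
  }
  ld_info(matrix = m)
}
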