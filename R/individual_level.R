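# Cohort-side analysis: sample/variant QC, residual + inverse-normal
# phenotype preprocessing, genetic-score construction, observational
# regression, the two-stage logistic (control-function) IV estimator and the
# three-stage mediation estimator.

#' Construct an individual-level cohort table
#'
#' @param dosages numeric matrix (samples x variants) of allele dosages in
#'   \[0, 2\], oriented to the trait-increasing allele, with variant ids as
#'   column names; `NA` dosages are allowed (scores mean-impute them).
#' @param samples data frame with a unique `sample_id` column plus
#'   covariates (e.g. `age`, `sex`, `pc1..pc5`, `batch`), quantitative
#'   phenotypes and binary outcome columns in \{0, 1\}.
#' @param info optional per-variant imputation-quality scores in \[0, 1\].
#' @param eaf optional per-variant effect-allele frequencies (used for
#'   mean imputation of missing dosages; estimated from the observed
#'   dosage mean when absent).
#' @return A `cohort_table` (list with elements `dosages`, `samples`,
#'   `info`, `eaf`).
#' @export
cohort_table <- function(dosages, samples, info = NULL, eaf = NULL) {
  stopifnot(is.matrix(dosages), is.data.frame(samples),
            "sample_id" %in% names(samples),
            nrow(dosages) == nrow(samples))
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id in cohort", call. = FALSE)
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("v", seq_len(ncol(dosages)))
  }
  if (!is.null(info)) {
    stopifnot(length(info) == ncol(dosages), all(info >= 0 & info <= 1))
    info <- setNames(info, colnames(dosages))
  }
  if (!is.null(eaf)) {
    stopifnot(length(eaf) == ncol(dosages))
    eaf <- setNames(eaf, colnames(dosages))
  }
  structure(list(dosages = dosages, samples = samples, info = info,
                 eaf = eaf),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d samples x %d variants; columns: %s\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(setdiff(names(x$samples), "sample_id"),
                    collapse = ", ")))
  invisible(x)
}

#' Sample and variant quality control
#'
#' Removes related samples (kinship coefficient above the threshold, or a
#' logical `kinship_flag` column), samples whose height lies more than
#' `height_sd_limit` SDs from the cohort mean, and variants whose
#' imputation-quality (INFO) score is below `info_threshold` (dropped
#' table-wide). Exclusion counts are logged by reason in the
#' `exclusion_log` attribute.
#'
#' @param cohort a [cohort_table()].
#' @param height_sd_limit SD window for the height outlier rule (default 5).
#' @param kinship_threshold kinship coefficient above which a sample counts
#'   as related (default 0.0884, the third-degree-relative cutoff).
#' @param info_threshold minimum imputation quality (default 0.4).
#' @param height_col name of the height phenotype column (default
#'   `"height"`).
#' @return The filtered `cohort_table` with attribute `exclusion_log`.
#' @export
qc_filter <- function(cohort, height_sd_limit = 5,
                      kinship_threshold = 0.0884, info_threshold = 0.4,
                      height_col = "height") {
  stopifnot(inherits(cohort, "cohort_table"))
  s <- cohort$samples
  if (!height_col %in% names(s)) {
    stop("height column '", height_col, "' not found", call. = FALSE)
  }
  related <- rep(FALSE, nrow(s))
  if ("kinship" %in% names(s)) {
    related <- !is.na(s$kinship) & s$kinship > kinship_threshold
  } else if ("kinship_flag" %in% names(s)) {
    related <- isTRUE_vec(s$kinship_flag)
  }
  ht <- s[[height_col]]
  mu <- mean(ht, na.rm = TRUE)
  sdev <- sd(ht, na.rm = TRUE)
  outlier <- !is.na(ht) & abs(ht - mu) > height_sd_limit * sdev
  keep_sample <- !related & !outlier
  if (!any(keep_sample)) {
    stop("qc_filter excluded every sample", call. = FALSE)
  }
  keep_variant <- if (is.null(cohort$info)) rep(TRUE, ncol(cohort$dosages))
  else cohort$info >= info_threshold
  log <- c(related = sum(related),
           height_outlier = sum(outlier & !related),
           low_info_variant = sum(!keep_variant))
  out <- cohort_table(cohort$dosages[keep_sample, keep_variant,
                                     drop = FALSE],
                      s[keep_sample, , drop = FALSE],
                      info = cohort$info[keep_variant],
                      eaf = cohort$eaf[keep_variant])
  attr(out, "exclusion_log") <- log
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Residualise and inverse-normalise a quantitative phenotype
#'
#' OLS residuals of the phenotype on the covariates, rank-transformed to
#' standard-normal quantiles via `qnorm((rank - 0.5)/n)` (average ranks for
#' ties). This puts exposures on the SD scale used throughout and limits
#' the influence of population structure; the output is invariant to any
#' strictly monotone transform of the input given fixed covariate effects
#' of zero.
#'
#' @param cohort a [cohort_table()].
#' @param phenotype phenotype column name.
#' @param covariates character vector of covariate column names (factors
#'   allowed, e.g. batch).
#' @return numeric vector (length = samples), mean ~ 0, SD ~ 1.
#' @export
residual_inverse_normalise <- function(cohort, phenotype, covariates) {
  stopifnot(inherits(cohort, "cohort_table"))
  s <- cohort$samples
  missing_cols <- setdiff(c(phenotype, covariates), names(s))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- s[[phenotype]]
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("phenotype '", phenotype, "' is constant; cannot transform",
         call. = FALSE)
  }
  fml <- stats::reformulate(covariates, response = phenotype)
  fit <- lm(fml, data = s, na.action = stats::na.exclude)
  res <- resid(fit)
  out <- rep(NA_real_, length(y))
  ok <- !is.na(res)
  r <- rank(res[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / sum(ok))
  out
}

#' Build a genetic score from allele dosages
#'
#' Unweighted: the per-sample sum of trait-increasing allele dosages.
#' Weighted: `sum(beta_j dosage_j)` rescaled by the mean effect size so the
#' range matches the unweighted score. Missing dosages are mean-imputed per
#' variant at `2 EAF` (logged in the `imputed` field).
#'
#' @param cohort a [cohort_table()] (dosages oriented to the
#'   trait-increasing allele).
#' @param weights optional named per-variant effect sizes; names must match
#'   the dosage columns exactly (any order). `NULL` gives the unweighted
#'   score.
#' @return A `genetic_score`: `kind`, `values`, `snps_used`,
#'   `rescale_factor` (weighted kind), `imputed` (count of imputed
#'   dosages).
#' @export
build_genetic_score <- function(cohort, weights = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  d <- cohort$dosages
  n_imputed <- 0L
  if (anyNA(d)) {
    eaf <- cohort$eaf %||% (colMeans(d, na.rm = TRUE) / 2)
    for (j in which(colSums(is.na(d)) > 0L)) {
      na_j <- is.na(d[, j])
      d[na_j, j] <- 2 * eaf[j]
      n_imputed <- n_imputed + sum(na_j)
    }
  }
  if (is.null(weights)) {
    values <- rowSums(d)
    out <- list(kind = "unweighted", values = values,
                snps_used = ncol(d), rescale_factor = NULL,
                imputed = n_imputed)
  } else {
    if (is.null(names(weights)) ||
        !setequal(names(weights), colnames(d)) ||
        length(weights) != ncol(d)) {
      stop("weights must be named and match the cohort variant set ",
           "exactly", call. = FALSE)
    }
    weights <- weights[colnames(d)]
    rescale <- mean(weights)
    values <- as.numeric(d %*% weights) / rescale
    out <- list(kind = "weighted", values = values, snps_used = ncol(d),
                rescale_factor = rescale, imputed = n_imputed)
  }
  structure(out, variant_ids = colnames(d), class = "genetic_score")
}

#' @export
print.genetic_score <- function(x, ...) {
  cat(sprintf("genetic_score (%s): %d SNPs, mean %.2f, range [%.2f, %.2f]\n",
              x$kind, x$snps_used, mean(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

new_stage_fit <- function(stage, fit, n) {
  sm <- summary(fit)
  structure(list(stage = stage,
                 coefficients = coef(sm),
                 fitted = stats::fitted(fit),
                 residuals = resid(fit),
                 n = n,
                 converged = if (!is.null(fit$converged)) fit$converged
                 else TRUE),
            class = "stage_fit")
}

#' @export
print.stage_fit <- function(x, ...) {
  cat(sprintf("stage_fit '%s' (n = %d, converged = %s)\n", x$stage, x$n,
              x$converged))
  print(round(x$coefficients, 5))
  invisible(x)
}

check_binary <- function(y, name) {
  yy <- y[!is.na(y)]
  if (!all(yy %in% c(0, 1))) {
    stop("outcome '", name, "' must be binary 0/1", call. = FALSE)
  }
}

check_separation <- function(fit, x_sd) {
  co <- coef(fit)
  std <- co[-1L] * x_sd
  if (any(!is.finite(co)) || any(abs(std) > 15, na.rm = TRUE)) {
    stop("separation suspected in logistic fit (standardized coefficient ",
         "magnitude > 15)", call. = FALSE)
  }
}

covariate_formula_part <- function(covariates) {
  if (length(covariates) == 0L) "1" else
    paste(covariates, collapse = " + ")
}

#' Observational (conventional) regression of disease on exposure
#'
#' Logistic regression of a binary outcome on the exposure standardized to
#' unit SD, adjusted for covariates; the conventional-epidemiology
#' comparator for the IV analyses.
#'
#' @param cohort a [cohort_table()].
#' @param outcome binary outcome column name.
#' @param exposure quantitative exposure column name (internally scaled to
#'   SD 1).
#' @param covariates covariate column names.
#' @return A `stage_fit` with extra fields `or`, `or_ci`, `log_or`,
#'   `log_or_se`, `pvalue` (per 1 SD of exposure).
#' @export
observational_association <- function(cohort, outcome, exposure,
                                      covariates = character(0)) {
  stopifnot(inherits(cohort, "cohort_table"))
  s <- cohort$samples
  check_binary(s[[outcome]], outcome)
  x <- s[[exposure]]
  if (length(unique(x[!is.na(x)])) < 2L) {
    stop("exposure '", exposure, "' is constant", call. = FALSE)
  }
  s$.exposure_sd <- x / sd(x, na.rm = TRUE)
  fml <- stats::as.formula(paste(outcome, "~ .exposure_sd +",
                                 covariate_formula_part(covariates)))
  fit <- glm(fml, family = binomial(), data = s)
  check_separation(fit, x_sd = 1)
  out <- new_stage_fit("observational", fit, sum(!is.na(s[[outcome]])))
  b <- coef(summary(fit))[".exposure_sd", ]
  out$log_or <- b[["Estimate"]]
  out$log_or_se <- b[["Std. Error"]]
  out$pvalue <- b[["Pr(>|z|)"]]
  out$or <- exp(out$log_or)
  out$or_ci <- exp(out$log_or + c(-1, 1) * qnorm(0.975) * out$log_or_se)
  out
}

fit_two_stage <- function(s, outcome, exposure, covariates, variant) {
  covs <- covariate_formula_part(covariates)
  s1 <- lm(stats::as.formula(paste(exposure, "~ .score +", covs)),
           data = s)
  s$.fitted_exposure <- stats::fitted(s1)
  s$.stage1_resid <- resid(s1)
  rhs <- if (variant == "control_function") {
    paste(".fitted_exposure + .stage1_resid +", covs)
  } else {
    paste(".fitted_exposure +", covs)
  }
  s2 <- glm(stats::as.formula(paste(outcome, "~", rhs)),
            family = binomial(), data = s)
  list(s1 = s1, s2 = s2,
       beta = coef(s2)[[".fitted_exposure"]])
}

#' Two-stage genetic-score instrumental-variable estimator
#'
#' Stage 1 regresses the exposure on the genetic score (plus covariates);
#' stage 2 is a logistic regression of disease status on the stage-1 fitted
#' values (plus covariates). The `control_function` variant (default) also
#' includes the stage-1 residual in stage 2, absorbing unmeasured
#' confounding shared between exposure and outcome; the `substitution`
#' variant uses the fitted values only. The coefficient on the fitted
#' exposure is the causal log-OR per unit exposure (per SD when the
#' exposure has been inverse-normalised). SEs come from a seeded
#' nonparametric bootstrap over samples (the stage-2 model-based SE, also
#' reported as `naive_se`, ignores first-stage uncertainty). A stage-1
#' F below 10 triggers a weak-instrument warning, never an error.
#'
#' @param cohort a [cohort_table()].
#' @param outcome binary outcome column.
#' @param exposure quantitative exposure column (use
#'   [residual_inverse_normalise()] output for SD-scale effects).
#' @param score a [build_genetic_score()] result (or numeric vector).
#' @param covariates covariate column names.
#' @param variant `"control_function"` (default) or `"substitution"`.
#' @param n_boot bootstrap replicates for the SE (default 200; 0 falls back
#'   to the naive SE).
#' @param seed RNG seed (required when `n_boot > 0`).
#' @return list with `stage1`, `stage2` (`stage_fit`s), `estimate` (an
#'   `mr_estimate`, method `two_stage_iv`), `f_stage1`, `naive_se`.
#' @export
two_stage_iv <- function(cohort, outcome, exposure, score,
                         covariates = character(0),
                         variant = c("control_function", "substitution"),
                         n_boot = 200L, seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(cohort, "cohort_table"))
  s <- cohort$samples
  check_binary(s[[outcome]], outcome)
  s$.score <- if (inherits(score, "genetic_score")) score$values else score
  keep <- complete.cases(s[c(outcome, exposure, covariates, ".score")])
  s <- s[keep, , drop = FALSE]

  fit <- fit_two_stage(s, outcome, exposure, covariates, variant)
  f1 <- coef(summary(fit$s1))[".score", "t value"]^2
  if (f1 < 10) {
    warning("weak instrument: stage-1 F = ", format(f1, digits = 3),
            " (< 10)", call. = FALSE)
  }
  check_separation(fit$s2, x_sd = sd(s$.fitted_exposure))
  naive_se <- coef(summary(fit$s2))[".fitted_exposure", "Std. Error"]

  se <- naive_se
  if (n_boot > 0L) {
    if (is.null(seed)) {
      stop("seed is required for the bootstrap SE", call. = FALSE)
    }
    betas <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        sb <- s[sample.int(nrow(s), replace = TRUE), , drop = FALSE]
        tryCatch(fit_two_stage(sb, outcome, exposure, covariates,
                               variant)$beta,
                 error = function(e) NA_real_)
      }, 0)
    })
    se <- sd(betas, na.rm = TRUE)
  }
  est <- new_mr_estimate("two_stage_iv", fit$beta, se,
                         n_snps = if (inherits(score, "genetic_score"))
                           score$snps_used else NA_integer_,
                         dist = "normal", outcome_type = "binary",
                         extra = list(variant = variant, f_stage1 = f1,
                                      naive_se = naive_se,
                                      n_boot = n_boot, seed = seed))
  list(stage1 = new_stage_fit("exposure~score", fit$s1, nrow(s)),
       stage2 = new_stage_fit("outcome~fitted", fit$s2, nrow(s)),
       estimate = est, f_stage1 = f1, naive_se = naive_se)
}

#' Three-stage mediation estimator (individual-level direct effect)
#'
#' Stages 1 and 2 fit the exposure and the mediator each on the full
#' instrument set (both genetic scores, plus covariates) — as in two-stage
#' least squares with two endogenous regressors — and stage 3 is a logistic
#' regression of disease on both sets of fitted values (plus covariates).
#' The coefficient on the fitted exposure is the direct effect of the
#' exposure not running through the mediator: predicting the mediator from
#' both scores lets its exposure-driven component absorb the mediated path.
#' The two scores should be built from disjoint variant sets
#' (overlap draws a warning); near-collinear fitted values (correlation
#' > 0.99) abort the fit.
#'
#' @param cohort a [cohort_table()].
#' @param outcome binary outcome column.
#' @param exposure,mediator quantitative phenotype columns.
#' @param exposure_score,mediator_score [build_genetic_score()] results or
#'   numeric vectors; if built from `genetic_score` objects the variant
#'   sets are checked for overlap via their `variant_ids` attribute when
#'   present.
#' @param covariates covariate column names.
#' @param n_boot optional nonparametric bootstrap replicates for the SE
#'   (default 0: analytic stage-3 SE, adequate when both scores are
#'   strong).
#' @param seed RNG seed (required when `n_boot > 0`).
#' @return list with the three `stage_fit`s and `estimate` (an
#'   `mr_estimate`, method `three_stage_direct`).
#' @export
three_stage_mediation <- function(cohort, outcome, exposure, mediator,
                                  exposure_score, mediator_score,
                                  covariates = character(0),
                                  n_boot = 0L, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  s <- cohort$samples
  check_binary(s[[outcome]], outcome)
  sc_e <- if (inherits(exposure_score, "genetic_score"))
    exposure_score$values else exposure_score
  sc_m <- if (inherits(mediator_score, "genetic_score"))
    mediator_score$values else mediator_score
  ids_e <- attr(exposure_score, "variant_ids")
  ids_m <- attr(mediator_score, "variant_ids")
  if (!is.null(ids_e) && !is.null(ids_m) &&
      length(intersect(ids_e, ids_m)) > 0L) {
    warning("exposure and mediator scores share variants; direct-effect ",
            "interpretation is weakened", call. = FALSE)
  }
  s$.score_e <- sc_e
  s$.score_m <- sc_m
  keep <- complete.cases(s[c(outcome, exposure, mediator, covariates,
                             ".score_e", ".score_m")])
  s <- s[keep, , drop = FALSE]
  covs <- covariate_formula_part(covariates)

  # each first stage uses the full instrument set (both scores): the
  # mediator prediction must include its exposure-driven component, or the
  # mediated path would load onto the fitted exposure and contaminate the
  # direct effect
  fit1 <- lm(stats::as.formula(paste(exposure,
                                     "~ .score_e + .score_m +", covs)),
             data = s)
  fit2 <- lm(stats::as.formula(paste(mediator,
                                     "~ .score_e + .score_m +", covs)),
             data = s)
  s$.fitted_e <- stats::fitted(fit1)
  s$.fitted_m <- stats::fitted(fit2)
  if (abs(stats::cor(s$.fitted_e, s$.fitted_m)) > 0.99) {
    stop("fitted exposure and mediator are collinear (|r| > 0.99); ",
         "scores do not separate the two traits", call. = FALSE)
  }
  fit3 <- glm(stats::as.formula(paste(outcome,
                                      "~ .fitted_e + .fitted_m +", covs)),
              family = binomial(), data = s)
  check_separation(fit3, x_sd = sd(s$.fitted_e))
  beta <- coef(fit3)[[".fitted_e"]]
  se <- coef(summary(fit3))[".fitted_e", "Std. Error"]
  if (n_boot > 0L) {
    if (is.null(seed)) {
      stop("seed is required for the bootstrap SE", call. = FALSE)
    }
    betas <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        sb <- s[sample.int(nrow(s), replace = TRUE), , drop = FALSE]
        f1 <- lm(stats::as.formula(paste(exposure,
                                         "~ .score_e + .score_m +", covs)),
                 data = sb)
        f2 <- lm(stats::as.formula(paste(mediator,
                                         "~ .score_e + .score_m +", covs)),
                 data = sb)
        sb$.fitted_e <- stats::fitted(f1)
        sb$.fitted_m <- stats::fitted(f2)
        f3 <- glm(stats::as.formula(paste(outcome,
                                          "~ .fitted_e + .fitted_m +",
                                          covs)),
                  family = binomial(), data = sb)
        coef(f3)[[".fitted_e"]]
      }, 0)
    })
    se <- sd(betas, na.rm = TRUE)
  }
  est <- new_mr_estimate("three_stage_direct", beta, se,
                         n_snps = NA_integer_, dist = "normal",
                         outcome_type = "binary",
                         extra = list(n_boot = n_boot, seed = seed))
  list(stage1 = new_stage_fit("exposure~score", fit1, nrow(s)),
       stage2 = new_stage_fit("mediator~score", fit2, nrow(s)),
       stage3 = new_stage_fit("outcome~fitted", fit3, nrow(s)),
       estimate = est)
}
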