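# Multivariable MR: direct effect of the exposure on the outcome adjusted
# for the per-instrument effects on candidate mediators, and the mediation
# decomposition of total vs direct effects.

mvmr_design <- function(h, mediators = NULL) {
  med_all <- attr(h, "mediators")
  mediators <- mediators %||% med_all
  missing_med <- setdiff(mediators, med_all)
  if (length(missing_med) > 0L) {
    stop("harmonized set lacks mediator column(s): ",
         paste(missing_med, collapse = ", "), call. = FALSE)
  }
  X <- cbind(exposure = h$beta_gx)
  for (lab in mediators) X <- cbind(X, h[[paste0("beta_gm_", lab)]])
  colnames(X) <- c("exposure", mediators)
  X
}

#' Multivariable IVW Mendelian randomisation
#'
#' Weighted multivariable regression of the variant-outcome effects on the
#' variant-exposure and variant-mediator effects, with no intercept
#' (instrument orientation makes the origin meaningful) and weights
#' `1/se_gy^2`. The exposure coefficient is the direct effect of the
#' exposure conditional on the mediators; SEs carry a multiplicative
#' overdispersion factor floored at 1, mirroring the univariable
#' random-effects convention. With zero mediator columns this reduces
#' exactly to univariable IVW.
#'
#' @param h a [harmonize()]d set carrying `beta_gm_*` / `se_gm_*` columns
#'   (from the `mediators` argument of [harmonize()]).
#' @param mediators which mediator labels to condition on (default: all
#'   present).
#' @return An `mvmr_estimate`: `exposure_beta`, `exposure_se`, `ci_low`,
#'   `ci_high`, `pvalue`, `mediator_betas`/`mediator_ses`,
#'   `conditioning_traits`, `n_snps`, `overdispersion`.
#' @export
mvmr_ivw <- function(h, mediators = NULL) {
  X <- mvmr_design(h, mediators)
  # an all-zero mediator column carries no conditioning information and
  # would only make the design singular; drop it (recorded)
  zero_med <- colnames(X)[-1L][colSums(abs(X[, -1L, drop = FALSE])) == 0]
  if (length(zero_med) > 0L) {
    X <- X[, setdiff(colnames(X), zero_med), drop = FALSE]
  }
  k <- ncol(X)
  if (nrow(h) < k + 1L) {
    stop("mvmr_ivw needs more instruments than exposures (J >= ", k + 1L,
         ")", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < k) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    stop("rank-deficient multivariable design: column(s) ",
         paste(dep, collapse = ", "),
         " are collinear with the others", call. = FALSE)
  }
  w <- 1 / h$se_gy^2
  fit <- lm.wfit(X, h$beta_gy, w)
  dfres <- nrow(h) - k
  scale <- max(1, sqrt(sum(w * fit$residuals^2) / dfres))
  cov_unscaled <- chol2inv(chol(crossprod(X * sqrt(w))))
  ses <- scale * sqrt(diag(cov_unscaled))
  beta <- fit$coefficients
  crit <- qnorm(0.975)
  structure(list(exposure_beta = beta[["exposure"]],
                 exposure_se = ses[1L],
                 ci_low = beta[["exposure"]] - crit * ses[1L],
                 ci_high = beta[["exposure"]] + crit * ses[1L],
                 pvalue = 2 * pnorm(-abs(beta[["exposure"]] / ses[1L])),
                 mediator_betas = beta[-1L],
                 mediator_ses = setNames(ses[-1L], colnames(X)[-1L]),
                 conditioning_traits = colnames(X)[-1L],
                 n_snps = nrow(h),
                 dropped_zero_mediators = zero_med,
                 overdispersion = scale,
                 outcome_type = attr(h, "outcome_type"),
                 instrument_hash = attr(h, "instrument_hash")),
            class = "mvmr_estimate")
}

mvmr_as_mr_estimate <- function(m) {
  e <- new_mr_estimate(paste0("mvmr_ivw[",
                              paste(m$conditioning_traits, collapse = "+"),
                              "]"),
                       m$exposure_beta, m$exposure_se, m$n_snps,
                       dist = "normal", outcome_type = m$outcome_type)
  e
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("mvmr_ivw direct effect (adjusting for %s):\n",
              paste(x$conditioning_traits, collapse = ", ")))
  cat(sprintf("  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, J = %d\n",
              x$exposure_beta, x$exposure_se, x$ci_low, x$ci_high,
              x$pvalue, x$n_snps))
  invisible(x)
}

#' Mediation decomposition of total vs direct effects
#'
#' Compares the univariable (total) estimate with the multivariable
#' (direct) estimate computed on the same instrument set and reports the
#' attenuation `100 (1 - beta_direct / beta_total)` on the log-OR scale,
#' alongside the OR-scale shift. The indirect effect is deliberately not
#' returned: with a binary outcome the product/difference decomposition
#' relies on a linearity that does not hold on the odds scale.
#'
#' @param total an `mr_estimate` from the univariable analysis.
#' @param direct an `mvmr_estimate` from [mvmr_ivw()] on the same
#'   harmonized set (enforced via the instrument-set fingerprint).
#' @param tolerance smallest `|beta_total|` for which the attenuation
#'   percentage is defined (default 1e-8).
#' @return A `mediation_summary`: `total`, `direct`, `attenuation_pct`
#'   (`NA` when `|beta_total|` is below tolerance), `or_shift`
#'   (`c(OR_total, OR_direct)` for binary outcomes).
#' @export
mediation_decomposition <- function(total, direct, tolerance = 1e-8) {
  stopifnot(inherits(total, "mr_estimate"),
            inherits(direct, "mvmr_estimate"))
  ht <- total$instrument_hash %||% attr(total, "instrument_hash")
  if (!is.null(ht) && !is.null(direct$instrument_hash) &&
      !identical(ht, direct$instrument_hash)) {
    stop("total and direct estimates come from different instrument sets",
         call. = FALSE)
  }
  att <- if (abs(total$beta) > tolerance) {
    100 * (1 - direct$exposure_beta / total$beta)
  } else NA_real_
  or_shift <- if (identical(total$outcome_type, "binary")) {
    c(OR_total = exp(total$beta), OR_direct = exp(direct$exposure_beta))
  } else NULL
  structure(list(total = total, direct = direct,
                 attenuation_pct = att, or_shift = or_shift),
            class = "mediation_summary")
}

#' @export
print.mediation_summary <- function(x, ...) {
  cat(sprintf("mediation: total beta = %.4f, direct beta = %.4f",
              x$total$beta, x$direct$exposure_beta))
  if (!is.na(x$attenuation_pct)) {
    cat(sprintf(" (attenuation %.1f%%)", x$attenuation_pct))
  }
  cat("\n")
  if (!is.null(x$or_shift)) {
    cat(sprintf("  OR shift: %.3f -> %.3f\n", x$or_shift[1L],
                x$or_shift[2L]))
  }
  invisible(x)
}

#' Conditional instrument-strength diagnostic for multivariable MR
#'
#' For each trait (the exposure and every mediator) the instrument effects
#' are regressed on the other traits' effects (weighted `1/se_gy^2`, no
#' intercept) and the mean F of the residual association is reported:
#' `mean((r_j / se_j)^2)` with `r_j` the residual effect and `se_j` the
#' trait's own effect SE. Low conditional F flags traits whose instruments
#' carry no information beyond the others'; the value is reported, never
#' used as a gate.
#'
#' @param h a [harmonize()]d set with at least one mediator column.
#' @return named numeric vector of conditional F statistics (exposure
#'   first).
#' @export
conditional_f_diagnostic <- function(h) {
  X <- mvmr_design(h)
  if (ncol(X) < 2L) {
    stop("conditional_f_diagnostic needs at least two exposure/mediator ",
         "columns", call. = FALSE)
  }
  se_cols <- c("se_gx",
               paste0("se_gm_", colnames(X)[-1L]))
  w <- 1 / h$se_gy^2
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  for (k in seq_len(ncol(X))) {
    yk <- X[, k]
    others <- X[, -k, drop = FALSE]
    r <- if (all(others == 0)) yk else {
      lm.wfit(others, yk, w)$residuals
    }
    out[k] <- mean((r / h[[se_cols[k]]])^2)
  }
  out
}
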