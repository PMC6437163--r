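# Summary-statistic causal estimators. All consume a harmonized_set (effects
# aligned to the exposure-increasing allele) and return mr_estimate objects
# on the outcome scale per 1 SD of exposure (log-OR for binary outcomes).

new_mr_estimate <- function(method, beta, se, n_snps,
                            dist = c("normal", "t"), df = NULL,
                            heterogeneity = NULL, outcome_type = NULL,
                            extra = list()) {
  dist <- match.arg(dist)
  if (dist == "t") {
    crit <- qt(0.975, df)
    pvalue <- 2 * pt(-abs(beta / se), df)
  } else {
    crit <- qnorm(0.975)
    pvalue <- 2 * pnorm(-abs(beta / se))
  }
  structure(c(list(method = method, beta = beta, se = se,
                   ci_low = beta - crit * se, ci_high = beta + crit * se,
                   pvalue = pvalue, n_snps = n_snps,
                   heterogeneity = heterogeneity,
                   outcome_type = outcome_type, dist = dist, df = df),
              extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, J = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue,
              x$n_snps))
  if (!is.null(x$or)) {
    cat(sprintf("  OR per 1 SD%s = %.3f [%.3f, %.3f]\n",
                if (is.null(x$sd_exposure_label)) "" else
                  paste0(" (", x$sd_exposure_label, ")"),
                x$or, x$or_ci_low, x$or_ci_high))
  }
  if (!is.null(x$heterogeneity)) {
    h <- x$heterogeneity
    cat(sprintf("  Q = %.2f (df %d, p = %.3g), I2 = %.1f%%\n",
                h$Q, h$df, h$pvalue, 100 * h$i2))
  }
  invisible(x)
}

#' Per-variant Wald ratio
#'
#' The variant-level causal estimate: the variant-outcome effect divided by
#' the variant-exposure effect, with either first-order delta-method SE
#' (`se_gy / |beta_gx|`, treating the exposure effect as known — the NOME
#' assumption) or second-order SE adding the exposure-side term of the
#' Taylor expansion.
#'
#' @param beta_gx,se_gx variant-exposure effect and SE (vectorised).
#' @param beta_gy,se_gy variant-outcome effect and SE.
#' @param weight_order `"first"` or `"second"`.
#' @param variant_id optional ids carried through.
#' @return data frame with columns `variant_id` (if given), `theta`,
#'   `se_theta`, `weight_order`.
#' @export
wald_ratio <- function(beta_gx, se_gx, beta_gy, se_gy,
                       weight_order = c("first", "second"),
                       variant_id = NULL) {
  weight_order <- match.arg(weight_order)
  if (any(beta_gx == 0)) {
    stop("degenerate instrument: beta_gx = 0 gives an undefined Wald ratio",
         call. = FALSE)
  }
  if (any(se_gy <= 0) || any(se_gx <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  theta <- beta_gy / beta_gx
  se_theta <- if (weight_order == "first") {
    se_gy / abs(beta_gx)
  } else {
    sqrt(se_gy^2 / beta_gx^2 + beta_gy^2 * se_gx^2 / beta_gx^4)
  }
  out <- data.frame(theta = theta, se_theta = se_theta,
                    weight_order = weight_order, stringsAsFactors = FALSE)
  if (!is.null(variant_id)) out <- cbind(variant_id = variant_id, out)
  out
}

ratio_estimates <- function(h, weight_order = "first") {
  wald_ratio(h$beta_gx, h$se_gx, h$beta_gy, h$se_gy,
             weight_order = weight_order, variant_id = h$variant_id)
}

#' Instrument-strength F statistic
#'
#' `(beta_gx / se_gx)^2`, the squared z/t of the variant-exposure
#' association; the conventional strength screen for instruments.
#'
#' @param beta_gx,se_gx effect and standard error (vectorised).
#' @return numeric vector of F statistics.
#' @export
f_statistic <- function(beta_gx, se_gx) {
  if (any(se_gx <= 0)) stop("se_gx must be positive", call. = FALSE)
  (beta_gx / se_gx)^2
}

check_min_instruments <- function(h, k, method) {
  if (nrow(h) < k) {
    stop(method, " requires at least ", k, " instruments (got ", nrow(h),
         ")", call. = FALSE)
  }
}

#' Inverse-variance weighted estimator
#'
#' Pools the per-variant Wald ratios with inverse-variance weights
#' `w_j = 1/se(theta_j)^2`; the point estimate equals a fixed-effect
#' meta-analysis of the ratios and, identically, weighted least squares of
#' `beta_gy` on `beta_gx` through the origin with weights `1/se_gy^2`.
#' `mode = "random"` applies a multiplicative overdispersion factor
#' `max(1, sqrt(Q/(J-1)))` to the SE; `mode = "second_order"` uses
#' second-order Wald-ratio SEs in the weights (the variant of the estimator
#' corrected for the exposure-side standard errors).
#'
#' @param h a [harmonize()]d set (>= 2 instruments).
#' @param mode `"fixed"`, `"random"` or `"second_order"`.
#' @return An `mr_estimate` (methods `ivw_fixed`, `ivw_random`, `ivw_2nd`)
#'   with Cochran's Q heterogeneity attached.
#' @export
ivw <- function(h, mode = c("fixed", "random", "second_order")) {
  mode <- match.arg(mode)
  check_min_instruments(h, 2L, "ivw")
  r <- ratio_estimates(h, if (mode == "second_order") "second" else "first")
  w <- 1 / r$se_theta^2
  beta <- sum(w * r$theta) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- sum(w * (r$theta - beta)^2)
  J <- nrow(h)
  het <- heterogeneity_stats(Q, J - 1L, w * (r$theta - beta)^2,
                             h$variant_id)
  se <- if (mode == "random") se_fixed * max(1, sqrt(Q / (J - 1))) else
    se_fixed
  method <- switch(mode, fixed = "ivw_fixed", random = "ivw_random",
                   second_order = "ivw_2nd")
  new_mr_estimate(method, beta, se, J, dist = "normal",
                  heterogeneity = het,
                  outcome_type = attr(h, "outcome_type"),
                  extra = list(instrument_hash = attr(h, "instrument_hash")))
}

#' MR-Egger regression
#'
#' Weighted regression of the variant-outcome effects on the
#' variant-exposure effects with an unconstrained intercept. The slope is
#' the causal estimate under the InSIDE assumption; a non-zero intercept
#' indicates directional pleiotropy. Inference uses a t reference with J - 2
#' df and a residual scale floored at 1 (the fit cannot claim more precision
#' than the sampling errors allow). Requires the orientation invariant of
#' [harmonize()] (all `beta_gx >= 0`). The regression-dilution diagnostic
#' [i2_gx()] is attached.
#'
#' @param h a [harmonize()]d set (>= 3 instruments).
#' @param weight_order `"first"` (weights `1/se_gy^2`) or `"second"`
#'   (weights `1/(se(theta_2nd)^2 beta_gx^2)`).
#' @param constrain_intercept internal check mode: with the intercept forced
#'   to zero the slope reproduces the fixed-effect IVW estimate.
#' @return An `egger_estimate`: list with `slope` (an `mr_estimate`),
#'   `intercept` (estimate, se, ci, p), `i2_gx`, `n_snps`.
#' @export
egger_regression <- function(h, weight_order = c("first", "second"),
                             constrain_intercept = FALSE) {
  weight_order <- match.arg(weight_order)
  check_min_instruments(h, 3L, "egger_regression")
  if (any(h$beta_gx < 0)) {
    stop("egger_regression requires effects oriented to the ",
         "exposure-increasing allele (all beta_gx >= 0)", call. = FALSE)
  }
  w <- if (weight_order == "first") {
    1 / h$se_gy^2
  } else {
    r2 <- ratio_estimates(h, "second")
    1 / (r2$se_theta^2 * h$beta_gx^2)
  }
  X <- if (constrain_intercept) cbind(beta_gx = h$beta_gx) else
    cbind(`(Intercept)` = 1, beta_gx = h$beta_gx)
  fit <- lm.wfit(X, h$beta_gy, w)
  J <- nrow(h)
  dfres <- J - ncol(X)
  rss_w <- sum(w * fit$residuals^2)
  scale <- max(1, sqrt(rss_w / dfres))
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  ses <- scale * sqrt(diag(XtWX_inv))

  slope_i <- ncol(X)
  slope <- new_mr_estimate("egger_slope", fit$coefficients[[slope_i]],
                           ses[slope_i], J, dist = "t", df = dfres,
                           outcome_type = attr(h, "outcome_type"))
  out <- list(slope = slope, n_snps = J, weight_order = weight_order,
              residual_scale = scale)
  if (!constrain_intercept) {
    b0 <- fit$coefficients[[1L]]
    se0 <- ses[1L]
    crit <- qt(0.975, dfres)
    out$intercept <- list(estimate = b0, se = se0,
                          ci_low = b0 - crit * se0,
                          ci_high = b0 + crit * se0,
                          pvalue = 2 * pt(-abs(b0 / se0), dfres))
    out$i2_gx <- i2_gx(h)
    slope$heterogeneity <- {
      w1 <- 1 / h$se_gy^2
      resid_q <- w1 * (h$beta_gy - b0 - slope$beta * h$beta_gx)^2
      heterogeneity_stats(sum(resid_q), J - 2L, resid_q, h$variant_id)
    }
    out$slope <- slope
  }
  structure(out, class = "egger_estimate")
}

#' @export
print.egger_estimate <- function(x, ...) {
  print(x$slope)
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.5f [%.5f, %.5f], p = %.3g; I2_GX = %.3f\n",
                x$intercept$estimate, x$intercept$ci_low,
                x$intercept$ci_high, x$intercept$pvalue, x$i2_gx))
  }
  invisible(x)
}

# point estimate of the inverse-variance weighted median: interpolate the
# ordered ratios at standardized cumulative weight 0.5
weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1L]) return(theta[1L])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  approx(s, theta, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap draws of (theta, w) matrices: exposure effects are
# redrawn around their observed values, outcome effects around the fitted
# ratio model (center_theta * beta_gx). Centering the outcome side on the
# fitted model rather than the observed effects avoids the noise-doubling
# over-dispersion of the observation-centered bootstrap, which would
# otherwise widen the ratio spread by sqrt(2) under homogeneity and make
# the median/mode SEs conservative.
boot_ratio_draws <- function(h, n_boot, center_theta) {
  J <- nrow(h)
  bx <- matrix(rnorm(n_boot * J, mean = rep(h$beta_gx, each = n_boot),
                     sd = rep(h$se_gx, each = n_boot)), n_boot, J)
  by <- matrix(rnorm(n_boot * J,
                     mean = rep(center_theta * h$beta_gx, each = n_boot),
                     sd = rep(h$se_gy, each = n_boot)), n_boot, J)
  bx[bx == 0] <- .Machine$double.eps
  theta <- by / bx
  w <- sweep(bx^2, 2L, h$se_gy^2, `/`)
  list(theta = theta, w = w)
}

#' Weighted median estimator
#'
#' Orders the Wald ratios and takes the inverse-variance weighted median:
#' consistent when more than 50% of the total weight comes from valid
#' (non-pleiotropic) instruments. The SE is the standard deviation of the
#' estimate over a seeded parametric bootstrap that redraws the exposure
#' effects around their observed values and the outcome effects around the
#' fitted ratio model (model-centered, so the ratio spread is not doubled
#' by re-adding outcome noise to already-noisy observations).
#'
#' @param h a [harmonize()]d set (>= 3 instruments).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed (required; the caller's RNG state is restored).
#' @return An `mr_estimate` (method `weighted_median`).
#' @export
weighted_median <- function(h, n_boot = 1000L, seed) {
  check_min_instruments(h, 3L, "weighted_median")
  r <- ratio_estimates(h, "first")
  w <- 1 / r$se_theta^2
  beta <- weighted_median_point(r$theta, w)
  se <- with_seed(seed, {
    d <- boot_ratio_draws(h, n_boot, center_theta = beta)
    sd(weighted_median_batch(d$theta, d$w))
  })
  new_mr_estimate("weighted_median", beta, se, nrow(h), dist = "normal",
                  outcome_type = attr(h, "outcome_type"),
                  extra = list(n_boot = n_boot, seed = seed))
}

# modified-Silverman bandwidth on the ratio scale; 0 signals exact atoms
# (repeated ratios), where the kernel mode degenerates to the heaviest atom
mbe_bandwidth <- function(theta, phi) {
  s <- 0.9 * min(sd(theta), mad(theta)) * length(theta)^(-1 / 5)
  if (!is.finite(s) || s < 0) s <- 0
  phi * s
}

#' Mode-based estimate
#'
#' The causal estimate is the mode of the normal-kernel-smoothed
#' distribution of the Wald ratios (weighted by `1/se(theta)^2` when
#' `weighted = TRUE`): consistent when the largest homogeneous cluster of
#' instruments is valid, even if they carry under half the weight. The
#' bandwidth is `phi` times a MAD-based default scale
#' (`0.9 min(sd, mad) J^{-1/5}`); the mode is located on a 512-point grid
#' spanning mean ± 5 SD of the ratios and refined by golden-section search
#' to tolerance 1e-8. SE via the same parametric bootstrap as
#' [weighted_median()].
#'
#' @param h a [harmonize()]d set (>= 3 instruments).
#' @param phi bandwidth multiplier (default 1).
#' @param weighted inverse-variance weight the kernel contributions
#'   (default TRUE).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed (required).
#' @param boot_grid_n grid resolution used inside the bootstrap (the point
#'   estimate always uses the full 512-point grid plus refinement).
#' @return An `mr_estimate` (method `mbe`) with the bandwidth in
#'   `$bandwidth`.
#' @export
mode_based_estimate <- function(h, phi = 1, weighted = TRUE,
                                n_boot = 1000L, seed,
                                boot_grid_n = 256L) {
  check_min_instruments(h, 3L, "mode_based_estimate")
  r <- ratio_estimates(h, "first")
  w <- if (weighted) 1 / r$se_theta^2 else rep(1, nrow(r))
  w <- w / sum(w)
  bw <- mbe_bandwidth(r$theta, phi)

  dens <- function(x) {
    vapply(x, function(xi) sum(w * dnorm(xi, r$theta, bw)), 0)
  }
  span_sd <- sd(r$theta)
  if (span_sd == 0 || bw == 0) {
    # degenerate/atomic ratio distribution: the mode is the heaviest atom
    atom_w <- tapply(w, r$theta, sum)
    beta <- as.numeric(names(atom_w)[which.max(atom_w)])
  } else {
    # grid plus the ratios themselves as candidates (a bandwidth narrower
    # than the grid step cannot hide a density spike between grid points),
    # then golden-section refinement around the best candidate
    grid <- seq(mean(r$theta) - 5 * span_sd, mean(r$theta) + 5 * span_sd,
                length.out = 512L)
    cand <- c(grid, r$theta)
    f <- dens(cand)
    x0 <- cand[which.max(f)]
    # refine within a bandwidth of the best candidate: the candidates
    # include every ratio, so the global mode lies within ~1 bandwidth of
    # one of them even when ratio outliers blow up the grid span; keep the
    # candidate if golden-section refinement does not improve on it
    opt <- optimize(dens, c(x0 - bw, x0 + bw), maximum = TRUE,
                    tol = 1e-8)
    beta <- if (opt$objective >= dens(x0)) opt$maximum else x0
  }

  se <- with_seed(seed, {
    d <- boot_ratio_draws(h, n_boot, center_theta = beta)
    wb <- if (weighted) d$w else matrix(1, nrow(d$theta), ncol(d$theta))
    hb <- apply(d$theta, 1L, mbe_bandwidth, phi = phi)
    sd(kernel_mode_batch(d$theta, wb, hb, as.integer(boot_grid_n), 5))
  })
  new_mr_estimate("mbe", beta, se, nrow(h), dist = "normal",
                  outcome_type = attr(h, "outcome_type"),
                  extra = list(bandwidth = bw, phi = phi,
                               weighted = weighted, n_boot = n_boot,
                               seed = seed))
}

#' Correlated-instrument IVW (generalised least squares)
#'
#' IVW accounting for residual LD between instruments: with outcome-side
#' covariance `Omega_ij = se_gy_i se_gy_j rho_ij` the estimate is
#' `(bx' Omega^-1 by) / (bx' Omega^-1 bx)` with SE
#' `sqrt(1 / (bx' Omega^-1 bx))`. With an identity LD matrix this equals the
#' fixed-effect IVW. A one-shot ridge adjustment (`1e-8` on the diagonal) is
#' applied if the Cholesky factorisation fails.
#'
#' @param h a [harmonize()]d set (>= 2 instruments).
#' @param ld an [ld_info()] in matrix form covering every instrument.
#' @return An `mr_estimate` (method `ivw_correlated`).
#' @export
ivw_correlated <- function(h, ld) {
  check_min_instruments(h, 2L, "ivw_correlated")
  rho <- ld_cor_matrix(ld, h$variant_id)
  omega <- tcrossprod(h$se_gy) * rho
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) {
    omega <- omega + diag(1e-8, nrow(omega))
    ch <- tryCatch(chol(omega), error = function(e) NULL)
    if (is.null(ch)) {
      stop("LD-adjusted weight matrix is not positive definite ",
           "(condition number ~ ", format(kappa(omega), digits = 3),
           ") beyond ridge tolerance", call. = FALSE)
    }
  }
  oinv_bx <- backsolve(ch, forwardsolve(t(ch), h$beta_gx))
  denom <- sum(h$beta_gx * oinv_bx)
  beta <- sum(oinv_bx * h$beta_gy) / denom
  se <- sqrt(1 / denom)
  new_mr_estimate("ivw_correlated", beta, se, nrow(h), dist = "normal",
                  outcome_type = attr(h, "outcome_type"))
}

#' Report an estimate on the odds-ratio scale
#'
#' For binary outcomes (betas on the log odds-ratio scale) attaches
#' `OR = exp(beta)` with exponentiated CI and an optional label describing
#' the exposure SD (e.g. "6.5 cm").
#'
#' @param e an `mr_estimate` with `outcome_type = "binary"`.
#' @param sd_exposure_label optional human-readable SD description.
#' @return The estimate with `or`, `or_ci_low`, `or_ci_high`,
#'   `sd_exposure_label` fields added.
#' @export
to_odds_ratio <- function(e, sd_exposure_label = NULL) {
  stopifnot(inherits(e, "mr_estimate"))
  if (identical(e$outcome_type, "quantitative")) {
    stop("odds-ratio scale is only defined for binary outcomes",
         call. = FALSE)
  }
  e$or <- exp(e$beta)
  e$or_ci_low <- exp(e$ci_low)
  e$or_ci_high <- exp(e$ci_high)
  e$sd_exposure_label <- sd_exposure_label
  e
}
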