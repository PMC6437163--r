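# Heterogeneity and horizontal-pleiotropy diagnostics, plus the two
# sensitivity filters (per-instrument Q-contribution exclusion and exclusion
# of mediator-associated variants) and a simplified residual-sum-of-squares
# outlier test.

heterogeneity_stats <- function(Q, df, per_variant_q, variant_ids = NULL) {
  structure(list(Q = Q, df = as.integer(df),
                 pvalue = pchisq(Q, df, lower.tail = FALSE),
                 i2 = max(0, (Q - df) / Q),
                 per_variant_q = setNames(per_variant_q, variant_ids)),
            class = "heterogeneity_stats")
}

#' Cochran's Q for the Wald ratios
#'
#' `Q = sum_j w_j (theta_j - beta_ref)^2` with first-order inverse-variance
#' weights, measured against a reference causal estimate (typically the
#' fixed-effect IVW; an Egger fit loses one further df). Excess Q signals
#' possible horizontal pleiotropy; it is quantified by
#' `I2 = max(0, (Q - df)/Q)`.
#'
#' @param h a [harmonize()]d set (>= 2 instruments).
#' @param reference an `mr_estimate` (or `egger_estimate`) providing the
#'   reference slope; defaults to fixed-effect IVW computed from `h`.
#' @return A `heterogeneity_stats` list: `Q`, `df`, `pvalue` (upper-tail
#'   chi-squared), `i2`, and named `per_variant_q` contributions summing to
#'   `Q`.
#' @export
cochran_q <- function(h, reference = NULL) {
  check_min_instruments(h, 2L, "cochran_q")
  if (is.null(reference)) reference <- ivw(h, "fixed")
  df_loss <- 1L
  if (inherits(reference, "egger_estimate")) {
    reference <- reference$slope
    df_loss <- 2L
  }
  r <- ratio_estimates(h, "first")
  w <- 1 / r$se_theta^2
  per_q <- w * (r$theta - reference$beta)^2
  heterogeneity_stats(sum(per_q), nrow(h) - df_loss, per_q, h$variant_id)
}

#' Regression-dilution diagnostic for MR-Egger (I2 of the exposure effects)
#'
#' Measures how far the variant-exposure effects stand out of their own
#' sampling noise: `Q_GX = sum v_j (beta_gx_j - mean_v)^2` with
#' `v_j = 1/se_gx_j^2`, returned as `max(0, (Q_GX - (J-1))/Q_GX)`. Values
#' near 1 mean the NOME assumption is benign and the Egger slope is not
#' attenuated by measurement error in the exposure effects.
#'
#' @param h a [harmonize()]d set (>= 2 instruments).
#' @return A value in \[0, 1\].
#' @export
i2_gx <- function(h) {
  check_min_instruments(h, 2L, "i2_gx")
  v <- 1 / h$se_gx^2
  bbar <- sum(v * h$beta_gx) / sum(v)
  q_gx <- sum(v * (h$beta_gx - bbar)^2)
  if (q_gx == 0) return(0)
  max(0, (q_gx - (nrow(h) - 1)) / q_gx)
}

q_level_thresholds <- c(L1 = 0.05, L2 = 0.01, L3 = 0.0019)

new_outlier_report <- function(h, keep, reasons, estimates_fun) {
  excluded <- data.frame(variant_id = h$variant_id[!keep],
                         reason = reasons[!keep], stringsAsFactors = FALSE)
  h_after <- subset_harmonized(h, keep)
  structure(list(excluded = excluded,
                 n_before = nrow(h), n_after = nrow(h_after),
                 estimates_before = estimates_fun(h),
                 estimates_after = if (nrow(h_after) >= 2L)
                   estimates_fun(h_after) else NULL,
                 harmonized_after = h_after),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier_report: %d of %d instruments excluded\n",
              nrow(x$excluded), x$n_before))
  if (nrow(x$excluded) > 0) {
    tab <- table(x$excluded$reason)
    cat("  reasons:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

default_filter_estimates <- function(h) {
  list(ivw_fixed = ivw(h, "fixed"), ivw_random = ivw(h, "random"))
}

#' Exclude instruments by per-variant Q contribution
#'
#' Per-instrument contributions to Cochran's Q (against the full-set
#' fixed-effect IVW estimate, computed once, not iteratively) are compared
#' with the upper-tail chi-squared(1) quantile at 5% (L1), 1% (L2) or 0.19%
#' (L3); instruments above the threshold are excluded and the estimates
#' recomputed on the remainder. Thresholds are monotone, so the L3
#' exclusions are a subset of L2's, which are a subset of L1's.
#'
#' @param h a [harmonize()]d set (>= 3 instruments).
#' @param level `"L1"`, `"L2"` or `"L3"`.
#' @param estimates_fun function of a harmonized set returning the estimates
#'   to recompute before/after (default: fixed- and random-effects IVW).
#' @return An `outlier_report`: excluded ids with reasons, before/after
#'   estimates, and the filtered set in `$harmonized_after`.
#' @export
q_contribution_filter <- function(h, level = c("L1", "L2", "L3"),
                                  estimates_fun = default_filter_estimates) {
  level <- match.arg(level)
  check_min_instruments(h, 3L, "q_contribution_filter")
  het <- cochran_q(h, ivw(h, "fixed"))
  threshold <- qchisq(q_level_thresholds[[level]], df = 1,
                      lower.tail = FALSE)
  keep <- het$per_variant_q <= threshold
  if (!any(keep)) {
    stop("q_contribution_filter at ", level,
         " excluded every instrument", call. = FALSE)
  }
  new_outlier_report(h, keep,
                     rep(paste0("q_", level), nrow(h)), estimates_fun)
}

#' Exclude instruments nominally associated with candidate mediators
#'
#' A variant is excluded when its p-value in any supplied mediator summary
#' table is strictly below the threshold; supplying several tables at once
#' gives the composite ("all traits") exclusion. Variants absent from a
#' mediator table are retained for that trait (and logged).
#'
#' @param h a [harmonize()]d set.
#' @param mediator_tables named list of [summary_table()]s.
#' @param p_threshold nominal association threshold (default 0.05,
#'   strict `<`).
#' @param estimates_fun as in [q_contribution_filter()].
#' @return An `outlier_report`; `$missing_log` names variants absent from
#'   each mediator table.
#' @export
mediator_exclusion_filter <- function(h, mediator_tables,
                                      p_threshold = 0.05,
                                      estimates_fun =
                                        default_filter_estimates) {
  stopifnot(is.list(mediator_tables), length(mediator_tables) > 0L)
  if (is.null(names(mediator_tables)) || any(names(mediator_tables) == "")) {
    names(mediator_tables) <- vapply(mediator_tables, attr, "",
                                     "trait_label")
  }
  reasons <- rep(NA_character_, nrow(h))
  missing_log <- list()
  for (lab in names(mediator_tables)) {
    tab <- mediator_tables[[lab]]
    idx <- match(h$variant_id, tab$variant_id)
    missing_log[[lab]] <- h$variant_id[is.na(idx)]
    hit <- !is.na(idx) & tab$pvalue[idx] < p_threshold
    reasons[hit & is.na(reasons)] <- lab
  }
  keep <- is.na(reasons)
  reasons[keep] <- "kept"
  report <- new_outlier_report(h, keep, reasons, estimates_fun)
  report$missing_log <- missing_log
  report
}

# leave-one-out fixed-effect IVW slopes, closed form (weights 1/se_gy^2)
loo_ivw_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' Residual-sum-of-squares global pleiotropy test (simplified)
#'
#' Observed statistic: `RSS = sum_j w_j (beta_gy_j - theta_(-j)
#' beta_gx_j)^2` with leave-one-out IVW slopes `theta_(-j)` and weights
#' `1/se_gy^2`. The null distribution is built by redrawing
#' `beta_gy_j ~ N(theta_(-j) beta_gx_j, se_gy_j)` and recomputing the
#' statistic (including the leave-one-out slopes) `n_sim` times; the global
#' p is the fraction of simulated RSS at or above the observed one.
#' Per-variant outlier p-values compare each observed contribution with its
#' simulated counterparts, Bonferroni-adjusted. The distortion test of the
#' full procedure is deliberately out of scope.
#'
#' @param h a [harmonize()]d set (>= 4 instruments).
#' @param n_sim null simulations (>= 100, default 1000).
#' @param seed RNG seed (required).
#' @return list with `rss_observed`, `global_p`, `per_variant_outlier_p`
#'   (Bonferroni-adjusted, named), `outliers` (ids with adjusted p < 0.05).
#' @export
presso_global_test <- function(h, n_sim = 1000L, seed) {
  check_min_instruments(h, 4L, "presso_global_test")
  if (n_sim < 100L) {
    stop("n_sim must be at least 100 for a usable null distribution",
         call. = FALSE)
  }
  J <- nrow(h)
  w <- 1 / h$se_gy^2
  theta_loo <- loo_ivw_slopes(h$beta_gx, h$beta_gy, w)
  contrib_obs <- w * (h$beta_gy - theta_loo * h$beta_gx)^2
  rss_obs <- sum(contrib_obs)

  sims <- with_seed(seed, {
    mu <- theta_loo * h$beta_gx
    by_sim <- matrix(rnorm(n_sim * J, mean = rep(mu, each = n_sim),
                           sd = rep(h$se_gy, each = n_sim)), n_sim, J)
    # leave-one-out slopes per simulated dataset, vectorised across rows
    wm <- matrix(w, n_sim, J, byrow = TRUE)
    bxm <- matrix(h$beta_gx, n_sim, J, byrow = TRUE)
    sxy <- rowSums(wm * bxm * by_sim)
    sxx <- sum(w * h$beta_gx^2)
    th <- (sxy - wm * bxm * by_sim) / (sxx - wm * bxm^2)
    wm * (by_sim - th * bxm)^2
  })
  rss_sim <- rowSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)
  per_p_raw <- (1 + colSums(sims >= rep(contrib_obs, each = n_sim))) /
    (1 + n_sim)
  per_p <- pmin(1, per_p_raw * J)
  names(per_p) <- h$variant_id
  list(rss_observed = rss_obs, global_p = global_p,
       per_variant_outlier_p = per_p,
       outliers = h$variant_id[per_p < 0.05],
       n_sim = n_sim, seed = seed)
}

#' Funnel-plot data export
#'
#' Per instrument, the Wald ratio and its precision `1/se(theta)`; under no
#' pleiotropy the points scatter symmetrically around the pooled estimate.
#' Reference estimates are carried as an attribute and written as `#`-prefixed
#' metadata lines by [write_funnel_data()].
#'
#' @param h a [harmonize()]d set.
#' @param references optional named list of `mr_estimate`s drawn as
#'   reference lines (default: fixed-effect IVW when J >= 2).
#' @return data frame `variant_id`, `theta`, `precision` with attribute
#'   `references` (named numeric).
#' @export
funnel_data <- function(h, references = NULL) {
  stopifnot(nrow(h) >= 1L)
  r <- ratio_estimates(h, "first")
  if (is.null(references)) {
    references <- if (nrow(h) >= 2L) list(ivw_fixed = ivw(h, "fixed")) else
      list()
  }
  ref <- vapply(references, function(e) {
    if (inherits(e, "egger_estimate")) e$slope$beta else e$beta
  }, 0)
  structure(data.frame(variant_id = h$variant_id, theta = r$theta,
                       precision = 1 / r$se_theta,
                       stringsAsFactors = FALSE),
            references = ref)
}

#' @rdname funnel_data
#' @param fd output of [funnel_data()].
#' @param path output file path.
#' @export
write_funnel_data <- function(fd, path) {
  ref <- attr(fd, "references")
  con <- file(path, "w")
  on.exit(close(con))
  if (length(ref) > 0) {
    writeLines(sprintf("# reference %s = %s", names(ref),
                       formatC(ref, digits = 12, format = "g")), con)
  }
  write.table(fd, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fd)
}
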