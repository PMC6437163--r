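# Wald ratio, F statistic, IVW, Egger, weighted median, MBE, correlated
# IVW, odds-ratio view — against closed forms and independent oracles.

test_that("Wald ratio arithmetic and delta-method SEs are exact, and the
          second-order SE matches a Monte-Carlo oracle", {
  w <- wald_ratio(0.1, 0.01, 0.05, 0.02, "first")
  expect_equal(w$theta, 0.5)
  expect_equal(w$se_theta, 0.2)

  w0 <- wald_ratio(1.0, 0.1, 0.0, 0.1, "first")
  expect_equal(w0$theta, 0)
  expect_equal(w0$se_theta, 0.1)

  expect_error(wald_ratio(0, 0.1, 0.1, 0.1), "degenerate")

  # Monte-Carlo oracle: empirical SD of the ratio over draws of
  # (beta_gx, beta_gy) from their sampling normals
  w2 <- wald_ratio(0.1, 0.005, 0.05, 0.02, "second")
  mc <- mrpath:::with_seed(101, {
    bx <- rnorm(1e6, 0.1, 0.005)
    by <- rnorm(1e6, 0.05, 0.02)
    sd(by / bx)
  })
  expect_equal(w2$se_theta, mc, tolerance = 0.01)
  expect_equal(w2$se_theta,
               sqrt(0.02^2 / 0.1^2 + 0.05^2 * 0.005^2 / 0.1^4))
})

test_that("F statistic is the squared z of the exposure association and
          matches a regression oracle", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0.02, 0.02), 1)
  expect_error(f_statistic(0.1, 0), "positive")

  # on a simulated genotype-phenotype regression it equals the squared
  # t statistic of the slope
  fit <- mrpath:::with_seed(7, {
    g <- rbinom(1e4, 2, 0.3)
    y <- 0.05 * g + rnorm(1e4)
    summary(lm(y ~ g))
  })
  b <- fit$coefficients["g", ]
  expect_equal(f_statistic(b[["Estimate"]], b[["Std. Error"]]),
               b[["t value"]]^2, tolerance = 1e-12)
})

test_that("IVW equals fixed-effect meta-analysis of Wald ratios and
          origin-constrained WLS; random effects floors at fixed", {
  # equal-weight pooling
  h2 <- make_harmonized(c(0.1, 0.1), c(0.001, 0.001), c(0.05, 0.05),
                        c(0.02, 0.02))
  e2 <- ivw(h2, "fixed")
  expect_equal(e2$beta, 0.5)
  expect_equal(e2$se, 0.2 / sqrt(2), tolerance = 1e-12)

  for (seed in 1:5) {
    h <- random_harmonized(J = 15L, theta = 0.3, seed = seed)
    e <- ivw(h, "fixed")
    # WLS through the origin with weights 1/se_gy^2
    wls <- lm(beta_gy ~ 0 + beta_gx, data = h, weights = 1 / h$se_gy^2)
    expect_equal(e$beta, unname(coef(wls)), tolerance = 1e-10)
    # fixed-effect meta-analysis of the ratios (closed form)
    r <- wald_ratio(h$beta_gx, h$se_gx, h$beta_gy, h$se_gy)
    w <- 1 / r$se_theta^2
    expect_equal(e$beta, sum(w * r$theta) / sum(w), tolerance = 1e-12)
    expect_equal(e$se, sqrt(1 / sum(w)), tolerance = 1e-12)
  }

  # independent meta-analysis oracle
  if (requireNamespace("metafor", quietly = TRUE)) {
    h <- random_harmonized(J = 25L, theta = -0.2, seed = 9L)
    r <- wald_ratio(h$beta_gx, h$se_gx, h$beta_gy, h$se_gy)
    fe <- metafor::rma(yi = r$theta, sei = r$se_theta, method = "FE")
    e <- ivw(h, "fixed")
    expect_equal(e$beta, as.numeric(fe$beta), tolerance = 1e-10)
    expect_equal(e$se, fe$se, tolerance = 1e-10)
  }

  # homogeneous data: Q < J - 1 leaves the random-effects SE at fixed
  h_hom <- make_harmonized(rep(0.1, 4), rep(0.001, 4),
                           rep(0.05, 4) + c(1, -1, 1, -1) * 1e-5,
                           rep(0.02, 4))
  expect_equal(ivw(h_hom, "random")$se, ivw(h_hom, "fixed")$se)

  # heterogeneous data inflate the random-effects SE
  h_het <- make_harmonized(rep(0.1, 4), rep(0.001, 4),
                           c(0.2, -0.1, 0.15, -0.05), rep(0.01, 4))
  expect_gt(ivw(h_het, "random")$se, ivw(h_het, "fixed")$se)

  expect_error(ivw(make_harmonized(0.1, 0.01, 0.05, 0.02)), "at least 2")
})

test_that("Egger regression recovers an exact affine relation, reduces to
          IVW when the intercept is constrained, and flags non-oriented
          input", {
  bx <- c(0.02, 0.04, 0.06, 0.08, 0.10)
  by <- 0.01 + 0.8 * bx
  h <- make_harmonized(bx, rep(0.002, 5), by, rep(0.01, 5))
  e <- egger_regression(h)
  expect_equal(e$slope$beta, 0.8, tolerance = 1e-10)
  expect_equal(e$intercept$estimate, 0.01, tolerance = 1e-10)
  expect_equal(e$residual_scale, 1)  # exact fit floors at 1
  expect_true(e$intercept$ci_low <= e$intercept$estimate &
                e$intercept$estimate <= e$intercept$ci_high)

  for (seed in 1:3) {
    hr <- random_harmonized(J = 12L, theta = 0.2, seed = seed)
    con <- egger_regression(hr, constrain_intercept = TRUE)
    expect_equal(con$slope$beta, ivw(hr, "fixed")$beta, tolerance = 1e-10)
  }

  h_neg <- make_harmonized(c(-0.02, 0.04, 0.06), rep(0.002, 3),
                           c(0.01, 0.02, 0.03), rep(0.01, 3))
  expect_error(egger_regression(h_neg), "oriented")
  expect_error(egger_regression(h[1:2, ]), "at least 3")
})

test_that("weighted median interpolates the inverse-variance-ordered
          ratios and its bootstrap SE is reasonable", {
  # equal weights, theta = {1, 2, 3}: midpoint lands on the middle ratio
  h3 <- make_harmonized(rep(0.1, 3), rep(0.001, 3),
                        c(0.1, 0.2, 0.3), rep(0.01, 3))
  e3 <- weighted_median(h3, n_boot = 100L, seed = 1L)
  expect_equal(e3$beta, 2)

  # all ratios identical: point estimate exact, SE near the pooled SE
  hid <- make_harmonized(rep(0.2, 6), rep(0.0005, 6), rep(0.1, 6),
                         rep(0.006, 6))
  eid <- weighted_median(hid, n_boot = 400L, seed = 2L)
  expect_equal(eid$beta, 0.5)
  pooled_se <- ivw(hid, "fixed")$se
  expect_equal(eid$se, pooled_se, tolerance = 0.35)

  # identical seed, identical result
  ea <- weighted_median(h3, n_boot = 100L, seed = 9L)
  eb <- weighted_median(h3, n_boot = 100L, seed = 9L)
  expect_identical(ea$se, eb$se)

  # the compiled batch kernel agrees with the R reference implementation
  set.seed(4)
  th <- matrix(rnorm(50), 5, 10)
  wm <- matrix(runif(50, 0.5, 2), 5, 10)
  got <- mrpath:::weighted_median_batch(th, wm)
  ref <- vapply(1:5, function(i)
    mrpath:::weighted_median_point(th[i, ], wm[i, ]), 0)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("mode-based estimate tracks the dominant cluster and its
          bandwidth scales linearly in phi", {
  # three identical ratios and one wild outlier: the mode is the repeated
  # value, untouched by the outlier
  h <- make_harmonized(rep(0.1, 4), rep(0.001, 4),
                       c(0.01, 0.01, 0.01, 0.5), rep(0.01, 4))
  e <- mode_based_estimate(h, n_boot = 100L, seed = 3L)
  expect_equal(e$beta, 0.1)

  # continuous ratios: doubling phi exactly doubles the bandwidth
  hc <- random_harmonized(J = 15L, theta = 0.2, seed = 6L)
  e1 <- mode_based_estimate(hc, n_boot = 100L, seed = 3L)
  e2 <- mode_based_estimate(hc, phi = 2, n_boot = 100L, seed = 3L)
  expect_gt(e1$bandwidth, 0)
  expect_equal(e2$bandwidth, 2 * e1$bandwidth, tolerance = 1e-12)

  ea <- mode_based_estimate(hc, n_boot = 100L, seed = 8L)
  eb <- mode_based_estimate(hc, n_boot = 100L, seed = 8L)
  expect_identical(ea$se, eb$se)
})

test_that("majority-invalid simulation: the mode tracks the largest valid
          cluster while the weighted median does not", {
  # 60% of instruments carry proportional pleiotropy split into two
  # sub-clusters of ratios (0.3 and 0.55); the single largest homogeneous
  # ratio cluster is the valid one at 0.1
  h <- mrpath:::with_seed(21, {
    J <- 60L
    bx <- runif(J, 0.05, 0.15)
    se_gy <- rep(0.002, J)
    slope_shift <- c(rep(0.2, 18), rep(0.45, 18), rep(0, 24))
    by <- (0.1 + slope_shift) * bx + rnorm(J, 0, se_gy)
    make_harmonized(bx, rep(0.001, J), by, se_gy)
  })
  mbe <- mode_based_estimate(h, n_boot = 100L, seed = 5L)
  wm <- weighted_median(h, n_boot = 100L, seed = 5L)
  expect_lt(abs(mbe$beta - 0.1), 0.05)
  expect_gt(abs(wm$beta - 0.1), abs(mbe$beta - 0.1))
})

test_that("correlated-instrument IVW reduces to fixed IVW under identity
          LD and to the single Wald estimate under perfect redundancy", {
  h <- random_harmonized(J = 8L, theta = 0.25, seed = 12L)
  m_id <- diag(8)
  dimnames(m_id) <- list(h$variant_id, h$variant_id)
  e_corr <- ivw_correlated(h, ld_info(matrix = m_id))
  e_fix <- ivw(h, "fixed")
  expect_equal(e_corr$beta, e_fix$beta, tolerance = 1e-12)
  expect_equal(e_corr$se, e_fix$se, tolerance = 1e-12)

  # two identical records with rho = 1 equal the single-instrument Wald
  h2 <- make_harmonized(c(0.1, 0.1), c(0.002, 0.002), c(0.05, 0.05),
                        c(0.01, 0.01))
  m <- matrix(1, 2, 2, dimnames = list(h2$variant_id, h2$variant_id))
  e_red <- ivw_correlated(h2, ld_info(matrix = m))
  expect_equal(e_red$beta, 0.5, tolerance = 1e-9)
  expect_equal(e_red$se, 0.01 / 0.1, tolerance = 1e-4)
})

test_that("LD-aware inference is calibrated under block LD while naive IVW
          understates uncertainty", {
  n_rep <- 120L
  ld <- simulate_ld_blocks(n_blocks = 10L, block_size = 4L, rho = 0.5)
  cover_corr <- cover_naive <- logical(n_rep)
  z_corr <- z_naive <- numeric(n_rep)
  theta <- 0.2
  for (r in seq_len(n_rep)) {
    cfg <- two_sample_config(n_snps = 40L, theta = theta,
                             n_exposure = 5e5, n_outcome = 5e5,
                             seed = 3000L + r)
    sim <- simulate_two_sample(cfg, ld = ld)
    h <- mrpath:::harmonized_from_sim(sim)
    ec <- ivw_correlated(h, ld)
    en <- ivw(h, "fixed")
    cover_corr[r] <- abs(ec$beta - theta) <= 1.96 * ec$se
    cover_naive[r] <- abs(en$beta - theta) <= 1.96 * en$se
    z_corr[r] <- abs(ec$beta - theta) / ec$se
    z_naive[r] <- abs(en$beta - theta) / en$se
  }
  expect_gte(mean(cover_corr), 0.90)
  expect_gte(mean(cover_corr), mean(cover_naive))
  expect_lt(mean(z_corr), mean(z_naive))  # smaller |z| accounting for LD
})

test_that("odds-ratio view exponentiates betas and CIs and round-trips", {
  h <- random_harmonized(J = 10L, theta = -0.1744, seed = 2L)
  e <- ivw(h, "fixed")
  e$beta <- -0.1744
  e$ci_low <- -0.22
  e$ci_high <- -0.13
  o <- to_odds_ratio(e, "6.5 cm")
  expect_equal(o$or, exp(-0.1744), tolerance = 1e-12)
  expect_equal(o$or, 0.840, tolerance = 1e-3)
  expect_equal(log(o$or), e$beta)
  expect_equal(o$or_ci_low, exp(-0.22))
  expect_equal(o$sd_exposure_label, "6.5 cm")

  e$beta <- 0
  e$ci_low <- -0.1
  e$ci_high <- 0.1
  o0 <- to_odds_ratio(e)
  expect_equal(o0$or, 1)
  expect_equal(o0$or_ci_low * o0$or_ci_high, 1, tolerance = 1e-12)

  eq <- e
  eq$outcome_type <- "quantitative"
  expect_error(to_odds_ratio(eq), "binary")
})

test_that("all estimators are equivariant under exposure rescaling", {
  h <- random_harmonized(J = 20L, theta = 0.15, seed = 31L)
  c0 <- 2.5
  h2 <- h
  h2$beta_gx <- c0 * h$beta_gx
  h2$se_gx <- c0 * h$se_gx
  attr(h2, "instrument_hash") <- attr(h, "instrument_hash")

  pairs <- list(
    list(ivw(h, "fixed"), ivw(h2, "fixed")),
    list(ivw(h, "random"), ivw(h2, "random")),
    list(ivw(h, "second_order"), ivw(h2, "second_order")),
    list(egger_regression(h)$slope, egger_regression(h2)$slope),
    list(weighted_median(h, n_boot = 200L, seed = 4L),
         weighted_median(h2, n_boot = 200L, seed = 4L)),
    list(mode_based_estimate(h, n_boot = 200L, seed = 4L),
         mode_based_estimate(h2, n_boot = 200L, seed = 4L)))
  for (p in pairs) {
    expect_equal(p[[2]]$beta, p[[1]]$beta / c0, tolerance = 1e-6)
    expect_equal(p[[2]]$se, p[[1]]$se / c0, tolerance = 0.05 * p[[1]]$se)
  }
})
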