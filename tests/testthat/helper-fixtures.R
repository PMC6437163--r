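# Shared fixture builders. All fixtures are constructed in code; no files.

# minimal well-formed association records
make_records <- function(n = 3L, beta = NULL, se = NULL, pvalue = NULL,
                         eaf = NULL, ea = "A", oa = "G") {
  data.frame(variant_id = sprintf("rs%03d", seq_len(n)),
             effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
             eaf = eaf %||% runif(n, 0.1, 0.45),
             beta = beta %||% rnorm(n, 0, 0.05),
             se = se %||% rep(0.01, n),
             pvalue = pvalue %||% runif(n, 1e-12, 0.99),
             n = 1e5, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_table <- function(..., trait_label = "trait",
                       trait_type = "quantitative") {
  summary_table(make_records(...), trait_label = trait_label,
                trait_type = trait_type)
}

# harmonized set straight from effect vectors (already oriented)
make_harmonized <- function(beta_gx, se_gx, beta_gy, se_gy,
                            outcome_type = "binary", mediators = NULL) {
  J <- length(beta_gx)
  h <- data.frame(variant_id = sprintf("rs%03d", seq_len(J)),
                  beta_gx = beta_gx, se_gx = se_gx,
                  beta_gy = beta_gy, se_gy = se_gy,
                  stringsAsFactors = FALSE)
  med_labels <- character(0)
  if (!is.null(mediators)) {
    for (lab in names(mediators)) {
      h[[paste0("beta_gm_", lab)]] <- mediators[[lab]]$beta
      h[[paste0("se_gm_", lab)]] <- mediators[[lab]]$se
    }
    med_labels <- names(mediators)
  }
  structure(h, outcome_type = outcome_type, mediators = med_labels,
            instrument_hash = mrpath:::fnv1a_hash(sort(h$variant_id)),
            class = c("harmonized_set", "data.frame"))
}

# a well-behaved random harmonized set for property checks
random_harmonized <- function(J = 20L, theta = 0.2, seed = 1L) {
  mrpath:::with_seed(seed, {
    bx <- abs(rnorm(J, 0, 0.05)) + 0.01
    se_gx <- runif(J, 0.002, 0.006)
    se_gy <- runif(J, 0.005, 0.02)
    by <- theta * bx + rnorm(J, 0, se_gy)
    make_harmonized(bx, se_gx, by, se_gy)
  })
}

# rebuild summary tables from a harmonized set (for idempotence checks)
tables_from_harmonized <- function(h) {
  ex <- summary_table(data.frame(variant_id = h$variant_id,
                                 effect_allele = "A", other_allele = "G",
                                 eaf = 0.3, beta = h$beta_gx, se = h$se_gx,
                                 pvalue = 2 * pnorm(-abs(h$beta_gx / h$se_gx)),
                                 n = 1e5),
                     trait_label = "exposure",
                     trait_type = "quantitative")
  out <- summary_table(data.frame(variant_id = h$variant_id,
                                  effect_allele = "A", other_allele = "G",
                                  eaf = 0.3, beta = h$beta_gy, se = h$se_gy,
                                  pvalue = pmax(2 * pnorm(-abs(h$beta_gy / h$se_gy)),
                                                1e-300),
                                  n = 1e5),
                      trait_label = "outcome", trait_type = "binary")
  list(exposure = ex, outcome = out)
}
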