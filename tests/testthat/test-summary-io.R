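# Reading, validation, harmonisation, LD pruning, results round trip.

test_that("reader parses canonical and dialect headers identically and
          enforces record invariants", {
  rec <- make_records(3L, beta = c(0.02, -0.01, 0.03), se = rep(0.01, 3))
  canonical <- file.path(tempdir(), "canonical.tsv")
  write.table(setNames(rec, c("SNP", "EA", "OA", "EAF", "BETA", "SE",
                              "P", "N")),
              canonical, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_summary_stats(canonical, trait_type = "quantitative",
                            trait_label = "trait")
  expect_s3_class(tab, "summary_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$beta, rec$beta)

  # GWAS-dialect headers via column_map give the identical table
  dialect <- file.path(tempdir(), "dialect.csv")
  write.table(setNames(rec, c("MarkerName", "A1", "A2", "Freq.A1", "b",
                              "se", "p", "N")),
              dialect, sep = ",", quote = FALSE, row.names = FALSE)
  tab2 <- read_summary_stats(dialect,
                             column_map = c(MarkerName = "variant_id",
                                            A1 = "effect_allele",
                                            A2 = "other_allele",
                                            Freq.A1 = "eaf", b = "beta",
                                            se = "se", p = "pvalue"),
                             trait_type = "quantitative",
                             trait_label = "trait")
  expect_equal(as.data.frame(tab2), as.data.frame(tab))

  # missing mandatory column is a configuration error naming the column
  broken <- file.path(tempdir(), "broken.tsv")
  write.table(rec[setdiff(names(rec), "se")], broken, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(broken), "se")

  # rows violating invariants are dropped and counted
  rec_bad <- make_records(4L)
  rec_bad$se[2L] <- 0
  tab3 <- summary_table(rec_bad, "t")
  expect_equal(nrow(tab3), 3L)
  expect_equal(unname(attr(tab3, "drop_log")["nonpositive_se"]), 1L)

  # lower-case alleles are upper-cased, not dropped
  rec_lc <- make_records(2L, ea = "a", oa = "g")
  expect_equal(summary_table(rec_lc, "t")$effect_allele, c("A", "A"))

  # an all-invalid table is an input error
  rec_all_bad <- make_records(2L, se = c(0, -1))
  expect_error(summary_table(rec_all_bad, "t"), "empty")
})

test_that("harmonisation aligns alleles, orients to the exposure-increasing
          allele, and is idempotent", {
  set.seed(42)
  ex <- make_table(5L, beta = c(0.03, -0.02, 0.05, 0.04, -0.01))
  out_rec <- make_records(5L, beta = c(0.01, 0.02, -0.03, 0.02, 0.005))
  out <- summary_table(out_rec, "outcome", "binary")
  h <- harmonize(ex, out)
  expect_true(all(h$beta_gx >= 0))
  expect_equal(nrow(h), 5L)

  # exposure beta_gx = -0.02 is re-oriented with beta_gy flipped in tandem
  i <- match("rs002", h$variant_id)
  expect_equal(h$beta_gx[i], 0.02)
  expect_equal(h$beta_gy[i], -0.02)

  # swapping outcome alleles and negating beta gives the identical set
  out_rec2 <- out_rec
  out_rec2$effect_allele <- "G"
  out_rec2$other_allele <- "A"
  out_rec2$beta <- -out_rec2$beta
  out_rec2$eaf <- 1 - out_rec2$eaf
  h2 <- harmonize(ex, summary_table(out_rec2, "outcome", "binary"))
  for (col in c("variant_id", "beta_gx", "se_gx", "beta_gy", "se_gy")) {
    expect_equal(h2[[col]], h[[col]])
  }

  # strand-complement coding of a non-palindromic variant also reconciles
  out_rec3 <- out_rec
  out_rec3$effect_allele <- "T"  # complement of A
  out_rec3$other_allele <- "C"   # complement of G
  h3 <- harmonize(ex, summary_table(out_rec3, "outcome", "binary"))
  expect_equal(h3$beta_gy, h$beta_gy)

  # idempotence: harmonising the already-harmonised tables changes nothing
  tabs <- tables_from_harmonized(h)
  h4 <- harmonize(tabs$exposure, tabs$outcome)
  expect_equal(h4$beta_gx, h$beta_gx)
  expect_equal(h4$beta_gy, h$beta_gy)

  # irreconcilable allele sets are dropped with a reason
  out_rec5 <- out_rec
  out_rec5$other_allele[3L] <- "C"
  h5 <- harmonize(ex, summary_table(out_rec5, "outcome", "binary"))
  expect_equal(nrow(h5), 4L)
  log5 <- attr(h5, "orientation_log")
  expect_equal(log5$reason[log5$variant_id == "rs003"], "allele_mismatch")

  # empty intersection is an input error
  ex_other <- make_table(3L)
  attr(ex_other, "trait_label") <- "x"
  ex_other$variant_id <- paste0("zz", 1:3)
  expect_error(harmonize(ex_other, out), "shared")
})

test_that("palindromic variants follow the configured policy", {
  rec <- make_records(2L, beta = c(0.02, 0.03), eaf = c(0.50, 0.20),
                      ea = "A", oa = "T")
  ex <- summary_table(rec, "exposure")
  out_rec <- make_records(2L, beta = c(0.01, -0.01), eaf = c(0.50, 0.80),
                          ea = "A", oa = "T")
  out <- summary_table(out_rec, "outcome", "binary")

  expect_error(harmonize(ex, out, palindromic_policy = "drop"), "remain")

  # infer_by_eaf: eaf 0.50 sits in the ambiguity window and is dropped with
  # reason "palindromic"; eaf 0.20 vs 0.80 implies opposite strands -> flip
  h <- harmonize(ex, out, palindromic_policy = "infer_by_eaf")
  expect_equal(h$variant_id, "rs002")
  expect_equal(h$beta_gy, 0.01)
  log <- attr(h, "orientation_log")
  expect_equal(log$reason[log$variant_id == "rs001"], "palindromic")
})

test_that("greedy LD pruning applies the r2 rule and matches exhaustive
          search on a chained-LD instance", {
  tab <- make_table(2L, beta = c(0.05, 0.04), se = c(0.005, 0.005),
                    pvalue = c(1e-10, 1e-8))
  ld_hi <- ld_info(pairs = data.frame(id_a = "rs001", id_b = "rs002",
                                      r2 = 0.06))
  kept <- ld_prune(tab, ld_hi)
  expect_equal(kept$variant_id, "rs001")
  ld_lo <- ld_info(pairs = data.frame(id_a = "rs001", id_b = "rs002",
                                      r2 = 0.04))
  expect_equal(nrow(ld_prune(tab, ld_lo)), 2L)

  # 10-variant chained-LD instance vs brute-force enumeration: the greedy
  # p-ordered rule must find a maximal valid set containing the smallest
  # p-values among the ties
  set.seed(11)
  J <- 10L
  tab10 <- make_table(J, pvalue = sort(runif(J, 1e-10, 1e-3)))
  pairs <- data.frame(id_a = tab10$variant_id[1:(J - 1)],
                      id_b = tab10$variant_id[2:J],
                      r2 = rep(c(0.2, 0.01), length.out = J - 1))
  ld <- ld_info(pairs = pairs)
  got <- ld_prune(tab10, ld)$variant_id

  # oracle: enumerate all subsets; valid = pairwise r2 <= threshold; the
  # greedy-by-p rule corresponds to picking, among maximum-size valid
  # subsets, the lexicographically smallest by p-order
  r2m <- mrpath:::ld_r2(ld, tab10$variant_id, tab10$variant_id)
  diag(r2m) <- 0
  lex_less <- function(a, b) {
    for (k in seq_len(min(length(a), length(b)))) {
      if (a[k] != b[k]) return(a[k] < b[k])
    }
    length(a) < length(b)
  }
  best <- NULL
  for (mask in seq_len(2^J) - 1L) {
    idx <- which(bitwAnd(mask, 2^(0:(J - 1))) > 0)
    if (length(idx) < length(best %||% integer(0))) next
    if (all(r2m[idx, idx] <= 0.05)) {
      if (is.null(best) || length(idx) > length(best) ||
          (length(idx) == length(best) && lex_less(idx, best))) {
        best <- idx
      }
    }
  }
  expect_setequal(got, tab10$variant_id[best])

  # permutation invariance: shuffling input rows leaves the kept set alone
  perm <- tab10[sample(J), ]
  class(perm) <- class(tab10)
  attr(perm, "trait_label") <- "trait"
  attr(perm, "trait_type") <- "quantitative"
  expect_setequal(ld_prune(perm, ld)$variant_id, got)

  # empty input passes through
  expect_equal(nrow(ld_prune(tab10[0, ], ld)), 0L)
})

test_that("results tables round-trip losslessly at 12 significant digits", {
  h <- random_harmonized(J = 12L, theta = -0.15, seed = 3L)
  ests <- list(ivw(h, "fixed"), ivw(h, "random"),
               egger_regression(h),
               weighted_median(h, n_boot = 50L, seed = 5L))
  path <- file.path(tempdir(), "results.tsv")
  written <- write_results(ests, path)
  back <- read_results(path)
  expect_equal(back$method, written$method)
  for (col in setdiff(names(written), "method")) {
    expect_equal(back[[col]], written[[col]], tolerance = 1e-11)
  }

  # single-instrument Wald rows have empty heterogeneity fields
  w <- wald_ratio(0.1, 0.01, 0.05, 0.02, variant_id = "rs1")
  e1 <- mrpath:::new_mr_estimate("wald", w$theta, w$se_theta, 1L,
                                 outcome_type = "binary")
  write_results(list(e1), path)
  line <- readLines(path)[2L]
  expect_match(line, "\t\t", fixed = TRUE)
  back1 <- read_results(path)
  expect_true(is.na(back1$Q))

  # empty collection gives a header-only file
  write_results(list(), path)
  expect_equal(length(readLines(path)), 1L)

  # unwritable path is an I/O error
  expect_error(write_results(ests, file.path(tempdir(), "no_dir", "x.tsv")),
               "cannot write")
})

test_that("downstream estimates are invariant to allele-label flips of an
          input table", {
  set.seed(99)
  ex <- make_table(8L, beta = rnorm(8, 0, 0.05), se = rep(0.004, 8))
  out_t <- summary_table(make_records(8L, beta = rnorm(8, 0, 0.01),
                                      se = rep(0.008, 8)),
                         "outcome", "binary")
  h_ref <- harmonize(ex, out_t)
  ref <- ivw(h_ref, "fixed")

  flipped <- as.data.frame(ex)
  flipped$effect_allele <- "G"
  flipped$other_allele <- "A"
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h_flip <- harmonize(summary_table(flipped, "exposure"), out_t)
  alt <- ivw(h_flip, "fixed")
  expect_equal(alt$beta, ref$beta, tolerance = 1e-12)
  expect_equal(alt$se, ref$se, tolerance = 1e-12)
})
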