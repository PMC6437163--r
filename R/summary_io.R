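# Reading, validation, harmonisation, LD pruning and serialisation of GWAS
# summary statistics. The canonical per-variant record carries the variant
# identifier, effect/other allele, effect-allele frequency, per-allele beta
# (SD units for quantitative traits, log-OR for binary traits), its standard
# error, p-value and sample size.

.canonical_fields <- c("variant_id", "effect_allele", "other_allele",
                       "eaf", "beta", "se", "pvalue", "n")
.canonical_headers <- c(variant_id = "SNP", effect_allele = "EA",
                        other_allele = "OA", eaf = "EAF", beta = "BETA",
                        se = "SE", pvalue = "P", n = "N")
.mandatory_fields <- c("variant_id", "effect_allele", "other_allele",
                       "beta", "se", "pvalue")

#' Construct a summary-statistics table
#'
#' Wraps a per-variant association data frame as a `summary_table`, the unit
#' consumed by harmonisation and by the MR estimators. Rows violating the
#' record invariants (alleles outside A/C/G/T or equal, `se <= 0`, `pvalue`
#' outside (0, 1], `eaf` outside (0, 1)) are dropped and counted in the
#' `drop_log` attribute.
#'
#' @param records data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue` and optionally `eaf`, `n`.
#' @param trait_label short trait name used in logs and reports.
#' @param trait_type `"quantitative"` (betas in SD units) or `"binary"`
#'   (betas on the log odds-ratio scale).
#' @return A `summary_table`: the validated data frame with attributes
#'   `trait_label`, `trait_type` and `drop_log` (named integer vector of
#'   drop counts by reason).
#' @export
summary_table <- function(records, trait_label,
                          trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.mandatory_fields, names(records))
  if (length(missing_cols) > 0L) {
    stop("summary table for '", trait_label, "' lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- records
  if (!"eaf" %in% names(rec)) rec$eaf <- NA_real_
  if (!"n" %in% names(rec)) rec$n <- NA_real_
  rec <- rec[.canonical_fields]
  rec$variant_id <- as.character(rec$variant_id)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "n")) {
    rec[[col]] <- suppressWarnings(as.numeric(rec[[col]]))
  }

  drop_log <- c(bad_allele = 0L, nonpositive_se = 0L, bad_pvalue = 0L,
                bad_eaf = 0L, missing_core = 0L, duplicate_id = 0L)
  ok_allele <- rec$effect_allele %in% c("A", "C", "G", "T") &
    rec$other_allele %in% c("A", "C", "G", "T") &
    rec$effect_allele != rec$other_allele
  ok_core <- !is.na(rec$variant_id) & rec$variant_id != "" &
    !is.na(rec$beta) & !is.na(rec$se) & !is.na(rec$pvalue)
  ok_se <- !is.na(rec$se) & rec$se > 0
  ok_p <- !is.na(rec$pvalue) & rec$pvalue > 0 & rec$pvalue <= 1
  ok_eaf <- is.na(rec$eaf) | (rec$eaf > 0 & rec$eaf < 1)

  drop_log["missing_core"] <- sum(!ok_core)
  drop_log["bad_allele"] <- sum(ok_core & !ok_allele)
  drop_log["nonpositive_se"] <- sum(ok_core & ok_allele & !ok_se)
  drop_log["bad_pvalue"] <- sum(ok_core & ok_allele & ok_se & !ok_p)
  drop_log["bad_eaf"] <- sum(ok_core & ok_allele & ok_se & ok_p & !ok_eaf)
  keep <- ok_core & ok_allele & ok_se & ok_p & ok_eaf
  rec <- rec[keep, , drop = FALSE]

  dup <- duplicated(rec$variant_id)
  drop_log["duplicate_id"] <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]
  rownames(rec) <- NULL

  if (nrow(rec) == 0L) {
    stop("summary table for '", trait_label,
         "' is empty after invariant filtering", call. = FALSE)
  }
  structure(rec, trait_label = trait_label, trait_type = trait_type,
            drop_log = drop_log,
            class = c("summary_table", "data.frame"))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row. Canonical headers
#' are `SNP, EA, OA, EAF, BETA, SE, P, N`; consortium dialects are handled by
#' `column_map`, a named character vector from file header to canonical field
#' name (e.g. `c(A1 = "effect_allele", b = "beta")`).
#'
#' @param path file path.
#' @param column_map optional named character vector mapping file column
#'   names to canonical field names (`variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`).
#' @param trait_type passed to [summary_table()].
#' @param trait_label trait name; defaults to the file name.
#' @return A [summary_table()]; invalid rows are dropped and counted in the
#'   `drop_log` attribute.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("quantitative", "binary"),
                               trait_label = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  nm <- names(raw)
  if (!is.null(column_map)) {
    if (is.null(names(column_map)) || any(names(column_map) == "")) {
      stop("column_map must be a fully named character vector", call. = FALSE)
    }
    bad <- setdiff(column_map, .canonical_fields)
    if (length(bad) > 0L) {
      stop("column_map targets unknown field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    hit <- match(nm, names(column_map))
    nm[!is.na(hit)] <- column_map[hit[!is.na(hit)]]
  }
  # canonical headers for anything not renamed by the map
  hit <- match(toupper(nm), .canonical_headers)
  nm[!is.na(hit)] <- names(.canonical_headers)[hit[!is.na(hit)]]
  names(raw) <- nm

  missing_cols <- setdiff(.mandatory_fields, nm)
  if (length(missing_cols) > 0L) {
    stop("input '", path, "' lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "),
         " (supply a column_map for dialect headers)", call. = FALSE)
  }
  summary_table(raw, trait_label = trait_label %||% basename(path),
                trait_type = trait_type)
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("summary_table '%s' (%s): %d variants\n",
              attr(x, "trait_label"), attr(x, "trait_type"), nrow(x)))
  dl <- attr(x, "drop_log")
  if (sum(dl) > 0) {
    cat("  dropped on read:",
        paste(sprintf("%s=%d", names(dl)[dl > 0], dl[dl > 0]),
              collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("  ...\n")
  invisible(x)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) .complement[ea] == oa

#' Harmonise exposure, outcome and mediator summary statistics
#'
#' Restricts to the shared variants, aligns outcome (and mediator) effects to
#' the exposure table's effect allele — flipping the beta sign and
#' complementing the EAF when the allele pair is swapped, recognising strand
#' (complement) codings — and finally re-orients every variant to the
#' exposure-increasing allele so that all `beta_gx >= 0`. Strand-ambiguous
#' (A/T, C/G) variants are handled per `palindromic_policy`: `"drop"`
#' excludes them; `"infer_by_eaf"` aligns by comparing allele frequencies,
#' dropping variants whose EAF falls in the ambiguity window \[0.42, 0.58\]
#' (or is missing).
#'
#' @param exposure,outcome [summary_table()] objects.
#' @param mediators optional named list of [summary_table()] objects whose
#'   aligned effects are carried as `beta_gm_<label>` / `se_gm_<label>`
#'   columns for multivariable MR.
#' @param palindromic_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @return A `harmonized_set`: data frame with columns `variant_id`,
#'   `beta_gx`, `se_gx`, `beta_gy`, `se_gy` (plus mediator columns), and
#'   attributes `orientation_log` (per-variant action and reason),
#'   `outcome_type`, `mediators` and `instrument_hash`.
#' @export
harmonize <- function(exposure, outcome, mediators = NULL,
                      palindromic_policy = c("infer_by_eaf", "drop")) {
  palindromic_policy <- match.arg(palindromic_policy)
  stopifnot(inherits(exposure, "summary_table"),
            inherits(outcome, "summary_table"))
  if (!is.null(mediators)) {
    stopifnot(is.list(mediators), length(mediators) > 0L)
    if (is.null(names(mediators)) || any(names(mediators) == "")) {
      names(mediators) <- vapply(mediators, attr, "", "trait_label")
    }
    lapply(mediators, function(m) stopifnot(inherits(m, "summary_table")))
  }

  ids <- intersect(exposure$variant_id, outcome$variant_id)
  if (!is.null(mediators)) {
    for (m in mediators) ids <- intersect(ids, m$variant_id)
  }
  if (length(ids) == 0L) {
    stop("no shared variants between exposure and outcome tables",
         call. = FALSE)
  }

  ex <- exposure[match(ids, exposure$variant_id), , drop = FALSE]

  # align one table's records to the exposure allele orientation;
  # returns aligned beta/se plus a per-variant status
  align_to <- function(tab) {
    rec <- tab[match(ids, tab$variant_id), , drop = FALSE]
    status <- rep("kept", length(ids))
    beta <- rec$beta
    same <- rec$effect_allele == ex$effect_allele &
      rec$other_allele == ex$other_allele
    swapped <- rec$effect_allele == ex$other_allele &
      rec$other_allele == ex$effect_allele
    flip_same <- .complement[rec$effect_allele] == ex$effect_allele &
      .complement[rec$other_allele] == ex$other_allele
    flip_swapped <- .complement[rec$effect_allele] == ex$other_allele &
      .complement[rec$other_allele] == ex$effect_allele
    pal <- is_palindromic(ex$effect_allele, ex$other_allele)

    # non-palindromic: strand flips resolve unambiguously
    ok_as_is <- !pal & (same | flip_same)
    ok_flip <- !pal & (swapped | flip_swapped)
    beta[ok_flip] <- -beta[ok_flip]
    status[ok_flip] <- "flipped"
    mismatch <- !pal & !ok_as_is & !ok_flip
    status[mismatch] <- "dropped:allele_mismatch"

    if (any(pal)) {
      if (palindromic_policy == "drop") {
        status[pal] <- "dropped:palindromic"
      } else {
        # for a palindromic variant all four codings name the same pair;
        # orientation is inferred from which side of 0.5 the EAFs fall
        valid_pair <- (same | swapped | flip_same | flip_swapped)
        ambiguous <- is.na(ex$eaf) | is.na(rec$eaf) |
          (ex$eaf >= 0.42 & ex$eaf <= 0.58) |
          (rec$eaf >= 0.42 & rec$eaf <= 0.58)
        flip_pal <- pal & valid_pair & !ambiguous &
          ((ex$eaf < 0.5) != (rec$eaf < 0.5))
        keep_pal <- pal & valid_pair & !ambiguous & !flip_pal
        beta[flip_pal] <- -beta[flip_pal]
        status[pal & valid_pair & ambiguous] <- "dropped:palindromic"
        status[pal & !valid_pair] <- "dropped:allele_mismatch"
        status[flip_pal] <- "flipped"
        status[keep_pal] <- "kept"
      }
    }
    list(beta = beta, se = rec$se, status = status)
  }

  out_al <- align_to(outcome)
  statuses <- list(outcome = out_al$status)
  med_al <- NULL
  if (!is.null(mediators)) {
    med_al <- lapply(mediators, align_to)
    for (lab in names(med_al)) statuses[[lab]] <- med_al[[lab]]$status
  }
  dropped <- Reduce(`|`, lapply(statuses, function(s) startsWith(s, "dropped")))
  reason <- rep("kept", length(ids))
  for (s in statuses) {
    take <- startsWith(s, "dropped") & reason == "kept"
    reason[take] <- sub("^dropped:", "", s[take])
  }
  reason[!dropped & Reduce(`|`, lapply(statuses, function(s) s == "flipped"))] <-
    "allele_flip"

  h <- data.frame(variant_id = ids,
                  beta_gx = ex$beta, se_gx = ex$se,
                  beta_gy = out_al$beta, se_gy = out_al$se,
                  stringsAsFactors = FALSE)
  med_labels <- character(0)
  if (!is.null(med_al)) {
    med_labels <- names(med_al)
    for (lab in med_labels) {
      h[[paste0("beta_gm_", lab)]] <- med_al[[lab]]$beta
      h[[paste0("se_gm_", lab)]] <- med_al[[lab]]$se
    }
  }

  # re-orient to the exposure-increasing allele
  neg <- !dropped & h$beta_gx < 0
  flip_cols <- grep("^beta_", names(h), value = TRUE)
  h[neg, flip_cols] <- -h[neg, flip_cols]
  reason[neg & reason == "kept"] <- "oriented_to_increasing"
  reason[neg & reason == "allele_flip"] <- "allele_flip+oriented"

  orientation_log <- data.frame(variant_id = ids,
                                action = ifelse(dropped, "dropped",
                                                ifelse(reason == "kept",
                                                       "kept", "flipped")),
                                reason = reason, stringsAsFactors = FALSE)
  h <- h[!dropped, , drop = FALSE]
  rownames(h) <- NULL
  if (nrow(h) == 0L) {
    stop("no variants remain after allele harmonisation", call. = FALSE)
  }
  structure(h,
            orientation_log = orientation_log,
            outcome_type = attr(outcome, "trait_type"),
            exposure_label = attr(exposure, "trait_label"),
            outcome_label = attr(outcome, "trait_label"),
            mediators = med_labels,
            instrument_hash = fnv1a_hash(sort(h$variant_id)),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized_set: %d instruments, %s -> %s\n", nrow(x),
              attr(x, "exposure_label") %||% "exposure",
              attr(x, "outcome_label") %||% "outcome"))
  med <- attr(x, "mediators")
  if (length(med) > 0) cat("  mediator columns:",
                           paste(med, collapse = ", "), "\n")
  log <- attr(x, "orientation_log")
  if (!is.null(log)) {
    tab <- table(log$reason)
    cat("  orientation:", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = ", "), "\n")
  }
  invisible(x)
}

# Rebuild the instrument-set fingerprint after row subsetting.
subset_harmonized <- function(h, keep) {
  out <- h[keep, , drop = FALSE]
  rownames(out) <- NULL
  at <- attributes(h)
  for (nm in setdiff(names(at), c("names", "row.names", "class"))) {
    attr(out, nm) <- at[[nm]]
  }
  attr(out, "instrument_hash") <- fnv1a_hash(sort(out$variant_id))
  class(out) <- class(h)
  out
}

#' Pairwise LD information
#'
#' Either a 3-column pair list (`id_a`, `id_b`, `r2`) or a square correlation
#' matrix with variant identifiers as dimnames. Pairs absent from the pair
#' list are treated as independent (r² = 0): instrument sets are typically
#' pre-pruned, so missing pairs dominate.
#'
#' @param pairs data frame with columns `id_a`, `id_b`, `r2` (r² in \[0, 1\]).
#' @param matrix square correlation matrix, unit diagonal, entries in
#'   \[-1, 1\], with variant ids as row/column names.
#' @return An `ld_info` object.
#' @export
ld_info <- function(pairs = NULL, matrix = NULL) {
  if (is.null(pairs) == is.null(matrix)) {
    stop("supply exactly one of 'pairs' or 'matrix'", call. = FALSE)
  }
  if (!is.null(pairs)) {
    stopifnot(is.data.frame(pairs),
              all(c("id_a", "id_b", "r2") %in% names(pairs)))
    if (any(pairs$r2 < 0 | pairs$r2 > 1)) {
      stop("pairwise r2 values must lie in [0, 1]", call. = FALSE)
    }
    obj <- list(form = "pairs",
                pairs = data.frame(id_a = as.character(pairs$id_a),
                                   id_b = as.character(pairs$id_b),
                                   r2 = as.numeric(pairs$r2),
                                   stringsAsFactors = FALSE))
  } else {
    stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
              !is.null(rownames(matrix)))
    if (max(abs(matrix - t(matrix))) > 1e-8) {
      stop("LD matrix must be symmetric", call. = FALSE)
    }
    if (max(abs(diag(matrix) - 1)) > 1e-8) {
      stop("LD matrix must have unit diagonal", call. = FALSE)
    }
    if (any(abs(matrix) > 1 + 1e-8)) {
      stop("LD correlations must lie in [-1, 1]", call. = FALSE)
    }
    obj <- list(form = "matrix", matrix = matrix)
  }
  structure(obj, class = "ld_info")
}

# r^2 lookup between two sets of ids; unknown pairs are independent (0)
ld_r2 <- function(ld, ids_a, ids_b) {
  stopifnot(inherits(ld, "ld_info"))
  if (ld$form == "matrix") {
    m <- ld$matrix
    out <- matrix(0, length(ids_a), length(ids_b))
    ia <- match(ids_a, rownames(m))
    ib <- match(ids_b, colnames(m))
    ok_a <- !is.na(ia)
    ok_b <- !is.na(ib)
    out[ok_a, ok_b] <- m[ia[ok_a], ib[ok_b], drop = FALSE]^2
    return(out)
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  lut <- ld$pairs$r2
  names(lut) <- key(ld$pairs$id_a, ld$pairs$id_b)
  grid <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
  vals <- lut[key(grid$a, grid$b)]
  vals[is.na(vals)] <- 0
  out <- matrix(vals, length(ids_a), length(ids_b))
  out[ids_a == rep(ids_b, each = length(ids_a))] <- 1
  out
}

# Correlation (not squared) matrix for a set of instruments; requires matrix
# form, used by the correlated-instrument estimator.
ld_cor_matrix <- function(ld, ids) {
  stopifnot(inherits(ld, "ld_info"))
  if (ld$form != "matrix") {
    stop("a square LD correlation matrix is required here", call. = FALSE)
  }
  idx <- match(ids, rownames(ld$matrix))
  if (anyNA(idx)) {
    stop("LD matrix lacks variant(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ld$matrix[idx, idx, drop = FALSE]
}

#' Greedy LD pruning of a summary table
#'
#' Variants are visited in order of ascending p-value (ties broken by larger
#' `|beta|/se`, then lexicographic id, so the result is deterministic); a
#' variant is accepted iff its r² with every already-accepted variant is at
#' or below the threshold. When two or more variants are in LD this keeps
#' only the most strongly associated one.
#'
#' @param table a [summary_table()].
#' @param ld an [ld_info()]; pairs absent from a pair list count as r² = 0.
#' @param r2_threshold maximum r² tolerated between retained variants
#'   (default 0.05).
#' @return A [summary_table()] restricted to the accepted variants, in
#'   acceptance order, with a `pruned_ids` attribute listing removals.
#' @export
ld_prune <- function(table, ld, r2_threshold = 0.05) {
  stopifnot(inherits(table, "summary_table"), inherits(ld, "ld_info"))
  if (nrow(table) == 0L) return(table)
  ord <- order(table$pvalue, -abs(table$beta) / table$se, table$variant_id)
  tab <- table[ord, , drop = FALSE]
  accepted <- integer(0)
  for (i in seq_len(nrow(tab))) {
    if (length(accepted) == 0L) {
      accepted <- i
      next
    }
    r2 <- ld_r2(ld, tab$variant_id[i], tab$variant_id[accepted])
    if (all(r2 <= r2_threshold)) accepted <- c(accepted, i)
  }
  out <- tab[accepted, , drop = FALSE]
  rownames(out) <- NULL
  at <- attributes(table)
  attr(out, "trait_label") <- at$trait_label
  attr(out, "trait_type") <- at$trait_type
  attr(out, "drop_log") <- at$drop_log
  attr(out, "pruned_ids") <- setdiff(table$variant_id, out$variant_id)
  class(out) <- class(table)
  out
}

.results_columns <- c("method", "n_snps", "beta", "se", "ci_low", "ci_high",
                      "p", "OR", "OR_ci_low", "OR_ci_high", "Q", "Q_p", "I2")

#' Collect MR estimates into a results table
#'
#' @param estimates a single estimate or list of `mr_estimate` /
#'   `egger_estimate` / `mvmr_estimate` objects.
#' @return data frame with one row per method: `method, n_snps, beta, se,
#'   ci_low, ci_high, p, OR, OR_ci_low, OR_ci_high, Q, Q_p, I2`.
#' @export
results_table <- function(estimates) {
  if (inherits(estimates, c("mr_estimate", "egger_estimate",
                            "mvmr_estimate"))) {
    estimates <- list(estimates)
  }
  rows <- lapply(estimates, function(e) {
    if (inherits(e, "egger_estimate")) e <- e$slope
    if (inherits(e, "mvmr_estimate")) e <- mvmr_as_mr_estimate(e)
    het <- e$heterogeneity
    binary <- identical(e$outcome_type, "binary")
    data.frame(method = e$method, n_snps = e$n_snps, beta = e$beta,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               p = e$pvalue,
               OR = if (binary) exp(e$beta) else NA_real_,
               OR_ci_low = if (binary) exp(e$ci_low) else NA_real_,
               OR_ci_high = if (binary) exp(e$ci_high) else NA_real_,
               Q = het$Q %||% NA_real_,
               Q_p = het$pvalue %||% NA_real_,
               I2 = het$i2 %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)),
                                      length(.results_columns)),
                                  .results_columns))
    out$method <- character(0)
  }
  out
}

#' Write MR estimates to delimited text
#'
#' One row per method; numeric fields are written at 12 significant digits so
#' the table round-trips losslessly through [read_results()]. Undefined
#' fields (e.g. Q for a single-instrument analysis) are written as empty
#' strings.
#'
#' @param estimates as for [results_table()] (or an already-built results
#'   data frame).
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return Invisibly, the written data frame.
#' @export
write_results <- function(estimates, path, sep = "\t") {
  tab <- if (is.data.frame(estimates)) estimates else results_table(estimates)
  fmt <- tab
  for (col in setdiff(names(fmt), c("method", "n_snps"))) {
    fmt[[col]] <- ifelse(is.na(tab[[col]]), "",
                         formatC(tab[[col]], digits = 12, format = "g"))
  }
  ok <- tryCatch({
    write.table(fmt, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write results to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(tab)
}

#' Read a results table written by [write_results()]
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data frame with the standard results columns; empty fields become
#'   `NA`.
#' @export
read_results <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = c(method = "character"))
  for (col in setdiff(.results_columns, c("method", "n_snps"))) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}
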