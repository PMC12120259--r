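#' Instrument-selection configuration
#'
#' Defaults follow common practice for summary-data MR with a relaxed
#' instrument threshold: p < 1e-5, clumping at r-squared < 0.001 within a
#' 10,000 kb window, and per-SNP F-statistic above 10.
#'
#' @param p_threshold keep variants with association p strictly below this.
#' @param clump_r2 r-squared above (or equal to) which nearby variants are
#'   pruned during clumping.
#' @param clump_window_kb clumping window in kilobases.
#' @param f_min retain variants with per-SNP F strictly above this.
#' @param confounder_snps character vector of SNP IDs known to associate
#'   with confounders; excluded before clumping.
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 1e-5, clump_r2 = 0.001,
                             clump_window_kb = 10000, f_min = 10,
                             confounder_snps = character()) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0, f_min >= 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 confounder_snps = as.character(confounder_snps)),
            class = "selection_config")
}

#' Filter a GWAS table by association p-value
#'
#' Keeps exactly the records with `pval` strictly below the threshold,
#' preserving row order.
#'
#' @param table a [gwas_table].
#' @param p_threshold numeric scalar in (0, 1].
#' @export
filter_by_pvalue <- function(table, p_threshold) {
  keep_rows(table, table$pval < p_threshold)
}

# Subset a gwas_table preserving its attributes.
keep_rows <- function(table, keep) {
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_id = attr(table, "trait_id"),
            trait_type = attr(table, "trait_type"),
            class = c("gwas_table", "data.frame"))
}

#' Greedy LD clumping
#'
#' Standard index-SNP clumping: variants are visited in ascending p-value
#' (ties broken lexicographically by SNP ID so the result does not depend
#' on input row order); each visited variant is kept and all unprocessed
#' variants on the same chromosome within the window whose r-squared with
#' it is at least `clump_r2` are removed. A pair absent from `ld` is
#' treated as r-squared 0 (independent), matching sparse LD exports.
#'
#' @param table a [gwas_table]; all records must carry `chrom` and `pos`.
#' @param ld an `ld_info` object or `NULL`.
#' @param clump_r2 pruning threshold on r-squared.
#' @param clump_window_kb window in kilobases within which pruning applies.
#' @return The clumped [gwas_table] (row order preserved from the input).
#' @export
ld_clump <- function(table, ld, clump_r2 = 0.001, clump_window_kb = 10000) {
  if (nrow(table) == 0) return(table)
  if (any(is.na(table$pos) | is.na(table$chrom))) {
    stop("record(s) missing position: ",
         paste(table$snp_id[is.na(table$pos) | is.na(table$chrom)], collapse = ", "))
  }
  ord <- order(table$pval, table$snp_id)
  status <- rep("pending", nrow(table))  # pending / kept / removed
  window_bp <- clump_window_kb * 1000
  for (i in ord) {
    if (status[i] != "pending") next
    status[i] <- "kept"
    cand <- which(status == "pending" &
                    table$chrom == table$chrom[i] &
                    abs(table$pos - table$pos[i]) <= window_bp)
    if (length(cand) > 0) {
      r2 <- ld_lookup(ld, table$snp_id[i], table$snp_id[cand])
      status[cand[r2 >= clump_r2]] <- "removed"
    }
  }
  keep_rows(table, status == "kept")
}

#' Variance in a trait explained by one SNP
#'
#' For a variant with effect-allele frequency `eaf` and per-allele effect
#' `beta` (trait in standardized units), R-squared = 2 EAF (1 - EAF) beta^2.
#'
#' @param eaf effect-allele frequency in (0, 1).
#' @param beta per-allele effect estimate.
#' @return numeric vector of R-squared values.
#' @export
snp_r2 <- function(eaf, beta) {
  if (any(!is.na(eaf) & (eaf <= 0 | eaf >= 1))) stop("eaf must lie in (0, 1)")
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument-strength F-statistic
#'
#' F = R-squared (n - k - 1) / (k (1 - R-squared)), where n is the sample
#' size and k the number of instruments; per-SNP use fixes k = 1. F > 10 is
#' the conventional cutoff against weak-instrument bias.
#'
#' @param r2 variance explained, in \[0, 1).
#' @param n sample size, must exceed k + 1.
#' @param k number of instruments (default 1 for per-SNP use).
#' @return numeric vector of F statistics.
#' @export
snp_f_stat <- function(r2, n, k = 1) {
  if (any(!is.na(r2) & (r2 < 0 | r2 >= 1))) stop("r2 must lie in [0, 1)")
  if (any(!is.na(n) & n <= k + 1)) stop("n must exceed k + 1")
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Select instruments for an exposure
#'
#' Applies, in order: the p-value filter, exclusion of SNPs on the
#' confounder list, greedy LD clumping, and the per-SNP F-statistic filter
#' (R-squared from [snp_r2] with the record's `eaf` and `beta`, F from
#' [snp_f_stat] with k = 1 and the record's `n`; records with missing `eaf`
#' cannot be scored and are removed at the F stage). An audit of removals
#' per stage is attached. Zero survivors is not an error: downstream
#' screening treats the empty set as "no instruments".
#'
#' @param table a [gwas_table] for the exposure.
#' @param ld an `ld_info` object or `NULL`.
#' @param cfg a [selection_config].
#' @return An object of class `instrument_set`: the surviving records with
#'   columns `r2` and `f_stat` appended, plus attributes `exposure_id`,
#'   `audit` (named removal counts) and `overall_f` (F recomputed with
#'   k = number of surviving instruments).
#' @export
select_instruments <- function(table, ld = NULL, cfg = selection_config()) {
  n0 <- nrow(table)
  t1 <- filter_by_pvalue(table, cfg$p_threshold)
  t2 <- keep_rows(t1, !(t1$snp_id %in% cfg$confounder_snps))
  t3 <- ld_clump(t2, ld, cfg$clump_r2, cfg$clump_window_kb)
  r2 <- ifelse(is.na(t3$eaf), NA_real_, snp_r2(t3$eaf, t3$beta))
  f <- ifelse(is.na(r2) | r2 >= 1, NA_real_, snp_r2_to_f(r2, t3$n))
  keep_f <- !is.na(f) & f > cfg$f_min
  out <- keep_rows(t3, keep_f)
  out$r2 <- r2[keep_f]
  out$f_stat <- f[keep_f]
  audit <- c(p_filter = n0 - nrow(t1),
             confounder = nrow(t1) - nrow(t2),
             clump = nrow(t2) - nrow(t3),
             f_filter = nrow(t3) - nrow(out))
  k <- nrow(out)
  overall_f <- if (k >= 1 && all(out$n > k + 1)) {
    mean(snp_f_stat(out$r2, out$n, k = k))
  } else NA_real_
  structure(out,
            exposure_id = attr(table, "trait_id"),
            audit = audit,
            overall_f = overall_f,
            class = c("instrument_set", class(out)))
}

snp_r2_to_f <- function(r2, n) r2 * (n - 2) / (1 - r2)

#' @export
print.instrument_set <- function(x, ...) {
  audit <- attr(x, "audit")
  cat(sprintf("Instrument set for '%s': %d SNPs\n", attr(x, "exposure_id"), nrow(x)))
  cat("  removed:", paste(sprintf("%s=%d", names(audit), audit), collapse = ", "), "\n")
  if (nrow(x) > 0) {
    cat(sprintf("  per-SNP F: min %.1f, median %.1f\n",
                min(x$f_stat), stats::median(x$f_stat)))
  }
  invisible(x)
}
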