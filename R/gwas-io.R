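#' GWAS summary-statistics tables
#'
#' A `gwas_table` is a validated data frame of per-variant association
#' summaries for a single trait: one row per SNP with effect and other
#' alleles, effect-allele frequency, effect estimate (log odds ratio for a
#' binary trait), its standard error, p-value and sample size.
#'
#' @param records data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` may be `NA` (such records are later ineligible for F-statistic
#'   and palindrome-frequency logic).
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`; for binary traits `beta`
#'   is interpreted on the log-odds scale.
#' @return An object of class `gwas_table`: the validated data frame with
#'   attributes `trait_id`, `trait_type` and `load_report` (rows kept /
#'   dropped per reason).
#' @export
gwas_table <- function(records, trait_id = "trait", trait_type = "continuous") {
  trait_type <- match.arg(trait_type, c("continuous", "binary"))
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[required]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  records$n <- as.integer(records$n)

  n_in <- nrow(records)
  bases <- c("A", "C", "G", "T")
  bad_allele <- !(records$effect_allele %in% bases) |
    !(records$other_allele %in% bases) |
    records$effect_allele == records$other_allele
  bad_eaf <- !is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1)
  bad_se <- is.na(records$se) | records$se <= 0
  bad_pval <- is.na(records$pval) | records$pval <= 0 | records$pval > 1
  bad_beta <- is.na(records$beta) | !is.finite(records$beta)
  invalid <- bad_allele | bad_eaf | bad_se | bad_pval | bad_beta
  invalid[is.na(invalid)] <- TRUE
  records <- records[!invalid, , drop = FALSE]

  dup <- duplicated(records$snp_id)
  records <- records[!dup, , drop = FALSE]
  rownames(records) <- NULL

  structure(records,
            trait_id = trait_id,
            trait_type = trait_type,
            load_report = c(kept = nrow(records),
                            invalid = sum(invalid),
                            duplicate = sum(dup),
                            total = n_in),
            class = c("gwas_table", "data.frame"))
}

#' @export
print.gwas_table <- function(x, ...) {
  rep <- attr(x, "load_report")
  cat(sprintf("GWAS summary statistics for '%s' (%s trait): %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  if (!is.null(rep) && rep[["invalid"]] + rep[["duplicate"]] > 0) {
    cat(sprintf("  load report: %d kept, %d invalid, %d duplicate of %d rows\n",
                rep[["kept"]], rep[["invalid"]], rep[["duplicate"]], rep[["total"]]))
  }
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

# Built-in column-dialect presets. A dialect maps the canonical field names
# onto a file's headers; unknown extra columns in the file are ignored.
.dialects <- list(
  default = c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
              effect_allele = "effect_allele", other_allele = "other_allele",
              eaf = "eaf", beta = "beta", se = "se", pval = "pval", n = "n"),
  gwas_catalog = c(snp_id = "variant_id", chrom = "chromosome",
                   pos = "base_pair_location", effect_allele = "effect_allele",
                   other_allele = "other_allele",
                   eaf = "effect_allele_frequency", beta = "beta",
                   se = "standard_error", pval = "p_value", n = "n"),
  finngen = c(snp_id = "rsids", chrom = "#chrom", pos = "pos",
              effect_allele = "alt", other_allele = "ref", eaf = "af_alt",
              beta = "beta", se = "sebeta", pval = "pval", n = "n")
)

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-separated file with a header, maps its columns onto the
#' canonical field names through a dialect, normalizes alleles to uppercase,
#' drops rows violating the record invariants (counted in the attached load
#' report) and returns a validated [gwas_table].
#'
#' @param path path to a TSV file.
#' @param dialect either the name of a built-in preset (`"default"`,
#'   `"gwas_catalog"`, `"finngen"`) or a named character vector mapping
#'   canonical names (`snp_id`, ..., `n`) to the file's headers.
#' @inheritParams gwas_table
#' @return A [gwas_table]; inspect `attr(x, "load_report")` for rows dropped.
#' @export
read_summary_stats <- function(path, dialect = "default",
                               trait_id = basename(path),
                               trait_type = "continuous") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(dialect) && length(dialect) == 1 && is.null(names(dialect))) {
    dialect <- .dialects[[match.arg(dialect, names(.dialects))]]
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  if (nrow(raw) == 0 && ncol(raw) == 0) stop("empty input file: ", path)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols) > 0) {
    stop("file lacks mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- raw[unname(dialect)]
  names(records) <- names(dialect)
  gwas_table(records, trait_id = trait_id, trait_type = trait_type)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Numbers are serialized at full precision (17 significant digits) so that
#' `read_summary_stats(write_summary_stats(x))` reproduces `x` exactly.
#'
#' @param table a [gwas_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(table, path) {
  df <- as.data.frame(table)
  for (col in c("eaf", "beta", "se", "pval")) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = TRUE)
    }, character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Pairwise linkage disequilibrium from a genotype dosage panel
#'
#' Computes r-squared for every variant pair as the squared Pearson
#' correlation of dosage columns (values in \[0, 2\]).
#'
#' @param panel numeric matrix, individuals in rows, variants in columns;
#'   column names are variant IDs.
#' @return An `ld_info` object: data frame with columns `snp_a`, `snp_b`,
#'   `r2`, one row per unordered pair (both orders resolvable via
#'   [ld_lookup]).
#' @export
ld_from_panel <- function(panel) {
  panel <- as.matrix(panel)
  if (nrow(panel) < 2) stop("need at least 2 individuals")
  if (is.null(colnames(panel))) stop("panel must carry variant IDs as column names")
  sds <- apply(panel, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant dosage column(s), LD undefined: ",
         paste(colnames(panel)[sds == 0], collapse = ", "))
  }
  r2 <- stats::cor(panel)^2
  idx <- which(upper.tri(r2), arr.ind = TRUE)
  ld_pairs(data.frame(snp_a = colnames(panel)[idx[, 1]],
                      snp_b = colnames(panel)[idx[, 2]],
                      r2 = r2[idx],
                      stringsAsFactors = FALSE))
}

#' Construct an LD-pair table
#'
#' @param pairs data frame with columns `snp_a`, `snp_b`, `r2` in \[0, 1\].
#'   Pairs are symmetric; missing pairs are treated as r2 = 0 downstream.
#' @return An `ld_info` object.
#' @export
ld_pairs <- function(pairs = data.frame(snp_a = character(), snp_b = character(),
                                        r2 = numeric())) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) stop("r2 outside [0, 1]")
  structure(pairs, class = c("ld_info", "data.frame"))
}

#' Look up r-squared for SNP pairs
#'
#' Symmetric lookup; `r2(a, a) = 1` and unlisted pairs return 0
#' (the sparse-export convention: absent means independent).
#'
#' @param ld an `ld_info` object (or `NULL`, meaning no LD anywhere).
#' @param a,b character vectors of SNP IDs (recycled to common length).
#' @return numeric vector of r-squared values.
#' @export
ld_lookup <- function(ld, a, b) {
  k <- max(length(a), length(b))
  a <- rep_len(as.character(a), k)
  b <- rep_len(as.character(b), k)
  out <- ifelse(a == b, 1, 0)
  if (!is.null(ld) && nrow(ld) > 0) {
    key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
    map <- ld$r2
    names(map) <- key(ld$snp_a, ld$snp_b)
    hit <- map[key(a, b)]
    out <- ifelse(a != b & !is.na(hit), hit, out)
  }
  unname(out)
}
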