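#' Is a variant palindromic?
#'
#' A palindromic (ambiguous-strand) SNP has complementary alleles, A/T or
#' C/G: strand orientation cannot be resolved from the alleles alone.
#'
#' @param effect_allele,other_allele single-base alleles (A, C, G or T).
#' @return logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  complement(effect_allele) == other_allele
}

complement <- function(x) {
  chartr("ACGT", "TGCA", toupper(x))
}

#' Harmonize exposure and outcome summary statistics
#'
#' Matches variants by SNP ID and places outcome effects on the exposure's
#' effect-allele convention. Outcome alleles equal to the exposure's are
#' kept as-is; swapped alleles flip the outcome beta's sign (and replace
#' the outcome EAF by 1 - EAF); strand flips (e.g. A/G recorded as T/C)
#' are reconciled via the complement before comparison. Palindromic (A/T,
#' C/G) variants are dropped by default because their strand cannot be
#' resolved; `palindrome_rescue = TRUE` retains a palindromic variant when
#' both studies' EAFs (after label alignment) lie outside the ambiguous
#' band and agree on the minor allele, applying a strand flip when they
#' disagree. Variants whose allele sets cannot be reconciled are dropped
#' as incompatible.
#'
#' @param exposure,outcome [gwas_table] objects (the exposure may be an
#'   `instrument_set`).
#' @param palindrome_rescue logical; frequency-based rescue of palindromic
#'   variants (default `FALSE`: all palindromes are eliminated).
#' @param eaf_ambiguous interval around 0.5 within which a palindromic
#'   variant's frequency is considered uninformative for rescue.
#' @return An object of class `harmonized_set`: data frame of kept pairs
#'   with columns `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta_exp`, `se_exp`, `pval_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `pval_out`, `eaf_out`, `action`; attributes `exposure_id`,
#'   `outcome_id` and `drop_log` (counts by action, including unmatched
#'   SNPs on both sides).
#' @export
harmonize <- function(exposure, outcome, palindrome_rescue = FALSE,
                      eaf_ambiguous = c(0.42, 0.58)) {
  edf <- as.data.frame(exposure)
  odf <- as.data.frame(outcome)
  m <- match(edf$snp_id, odf$snp_id)
  keep_idx <- which(!is.na(m))
  n_unmatched <- (nrow(edf) - length(keep_idx)) +
    (nrow(odf) - length(keep_idx))
  e <- edf[keep_idx, , drop = FALSE]
  o <- odf[m[keep_idx], , drop = FALSE]
  k <- nrow(e)

  beta_out <- o$beta; eaf_out <- o$eaf
  action <- rep("dropped_incompatible", k)

  pal <- is_palindromic(e$effect_allele, e$other_allele)
  direct <- o$effect_allele == e$effect_allele & o$other_allele == e$other_allele
  swapped <- o$effect_allele == e$other_allele & o$other_allele == e$effect_allele
  sf_direct <- complement(o$effect_allele) == e$effect_allele &
    complement(o$other_allele) == e$other_allele
  sf_swapped <- complement(o$effect_allele) == e$other_allele &
    complement(o$other_allele) == e$effect_allele

  action[!pal & (direct | sf_direct)] <- "kept_as_is"
  action[!pal & (swapped | sf_swapped)] <- "flipped"

  if (any(pal)) {
    if (!palindrome_rescue) {
      action[pal] <- ifelse(direct[pal] | swapped[pal],
                            "dropped_palindromic", "dropped_incompatible")
    } else {
      # align outcome to the exposure's allele labels first, then use
      # minor-allele concordance to resolve strand
      lab_flip <- pal & swapped
      beta_out[lab_flip] <- -beta_out[lab_flip]
      eaf_out[lab_flip] <- 1 - eaf_out[lab_flip]
      informative <- !is.na(e$eaf) & !is.na(eaf_out) &
        (e$eaf <= eaf_ambiguous[1] | e$eaf >= eaf_ambiguous[2]) &
        (eaf_out <= eaf_ambiguous[1] | eaf_out >= eaf_ambiguous[2])
      ok <- pal & (direct | swapped) & informative
      strand_flip <- ok & ((e$eaf < 0.5) != (eaf_out < 0.5))
      beta_out[strand_flip] <- -beta_out[strand_flip]
      eaf_out[strand_flip] <- 1 - eaf_out[strand_flip]
      net_flip <- xor(lab_flip, strand_flip)
      action[ok] <- ifelse(net_flip[ok], "flipped", "kept_as_is")
      action[pal & (direct | swapped) & !informative] <- "dropped_palindromic"
    }
  }

  flip <- action == "flipped" & !pal  # palindromes already adjusted above
  beta_out[flip] <- -beta_out[flip]
  eaf_out[flip] <- ifelse(is.na(eaf_out[flip]), NA_real_, 1 - eaf_out[flip])

  kept <- action %in% c("kept_as_is", "flipped")
  pairs <- data.frame(
    snp_id = e$snp_id[kept], chrom = e$chrom[kept], pos = e$pos[kept],
    effect_allele = e$effect_allele[kept], other_allele = e$other_allele[kept],
    beta_exp = e$beta[kept], se_exp = e$se[kept],
    pval_exp = e$pval[kept], eaf_exp = e$eaf[kept],
    beta_out = beta_out[kept], se_out = o$se[kept],
    pval_out = o$pval[kept], eaf_out = eaf_out[kept],
    action = action[kept], stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  drop_log <- c(kept_as_is = sum(action == "kept_as_is"),
                flipped = sum(action == "flipped"),
                dropped_palindromic = sum(action == "dropped_palindromic"),
                dropped_incompatible = sum(action == "dropped_incompatible"),
                dropped_unmatched = n_unmatched)
  structure(pairs,
            exposure_id = attr(exposure, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            drop_log = drop_log,
            class = c("harmonized_set", "data.frame"))
}

#' Assemble a harmonized set directly from effect pairs
#'
#' Escape hatch for simulation and testing: builds a `harmonized_set` from
#' already-aligned exposure/outcome effect pairs without allele bookkeeping.
#'
#' @param beta_exp,se_exp,beta_out,se_out aligned effect estimates and SEs.
#' @param snp_id variant IDs (generated if omitted).
#' @param pval_exp,eaf_exp optional exposure p-values / frequencies.
#' @param exposure_id,outcome_id trait labels.
#' @return A `harmonized_set`.
#' @export
harmonized_pairs <- function(beta_exp, se_exp, beta_out, se_out,
                             snp_id = paste0("rs", seq_along(beta_exp)),
                             pval_exp = pval_normal(beta_exp, se_exp),
                             eaf_exp = NA_real_,
                             exposure_id = "exposure", outcome_id = "outcome") {
  stopifnot(all(se_exp > 0), all(se_out > 0))
  pairs <- data.frame(snp_id = snp_id, chrom = NA_character_, pos = NA_integer_,
                      effect_allele = NA_character_, other_allele = NA_character_,
                      beta_exp = beta_exp, se_exp = se_exp,
                      pval_exp = pval_exp, eaf_exp = eaf_exp,
                      beta_out = beta_out, se_out = se_out,
                      pval_out = pval_normal(beta_out, se_out),
                      eaf_out = NA_real_,
                      action = "kept_as_is", stringsAsFactors = FALSE)
  structure(pairs,
            exposure_id = exposure_id, outcome_id = outcome_id,
            drop_log = c(kept_as_is = nrow(pairs), flipped = 0L,
                         dropped_palindromic = 0L, dropped_incompatible = 0L,
                         dropped_unmatched = 0L),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  log <- attr(x, "drop_log")
  cat(sprintf("Harmonized set '%s' -> '%s': %d variants\n",
              attr(x, "exposure_id") %||% "exposure",
              attr(x, "outcome_id") %||% "outcome", nrow(x)))
  cat("  ", paste(sprintf("%s=%d", names(log), log), collapse = ", "), "\n")
  invisible(x)
}
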