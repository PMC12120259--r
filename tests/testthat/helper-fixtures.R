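# Small programmatic fixtures shared across tests.

# A well-formed GWAS table with n rows; deterministic content.
toy_gwas <- function(n = 5, trait_id = "toy", pval = NULL, chrom = NULL,
                     pos = NULL, beta = NULL, eaf = NULL,
                     effect_allele = NULL, other_allele = NULL,
                     n_sample = 5959) {
  gwas_table(data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = chrom %||% rep("1", n),
    pos = pos %||% (1000L + 100000L * seq_len(n)),
    effect_allele = effect_allele %||% rep("A", n),
    other_allele = other_allele %||% rep("G", n),
    eaf = eaf %||% rep(0.3, n),
    beta = beta %||% seq(0.1, by = 0.01, length.out = n),
    se = rep(0.02, n),
    pval = pval %||% rep(1e-8, n),
    n = rep(n_sample, n),
    stringsAsFactors = FALSE), trait_id = trait_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force greedy clumping oracle: re-derives the kept set by explicit
# iteration over p-ordered SNPs, independent of ld_clump's implementation.
clump_oracle <- function(df, r2_fun, clump_r2, window_bp) {
  ord <- order(df$pval, df$snp_id)
  kept <- character(); removed <- character()
  for (i in ord) {
    id <- df$snp_id[i]
    if (id %in% removed) next
    kept <- c(kept, id)
    for (j in seq_len(nrow(df))) {
      jd <- df$snp_id[j]
      if (jd %in% c(kept, removed)) next
      if (df$chrom[j] == df$chrom[i] &&
          abs(df$pos[j] - df$pos[i]) <= window_bp &&
          r2_fun(id, jd) >= clump_r2) {
        removed <- c(removed, jd)
      }
    }
  }
  kept
}

# Turn a harmonized set back into exposure/outcome gwas_tables on the
# exposure's allele convention (for idempotence checks).
tables_from_harmonized <- function(h) {
  base <- function(beta, se, pval, eaf, id) {
    gwas_table(data.frame(snp_id = h$snp_id, chrom = "1",
                          pos = 1000L + 100000L * seq_len(nrow(h)),
                          effect_allele = h$effect_allele,
                          other_allele = h$other_allele,
                          eaf = eaf, beta = beta, se = se, pval = pval,
                          n = 10000L, stringsAsFactors = FALSE),
               trait_id = id)
  }
  list(exposure = base(h$beta_exp, h$se_exp, h$pval_exp, h$eaf_exp, "exp"),
       outcome = base(h$beta_out, h$se_out, h$pval_out, h$eaf_out, "out"))
}
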