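#' Simulation configuration for summary-level GWAS triplets
#'
#' Describes a two-sample MR study with known causal structure
#' exposure -> mediator -> outcome. Default sample sizes follow the scale
#' of public gut-microbiota (n = 5959), blood-metabolite (n = 8299) and
#' biobank disease (n = 368519) GWAS; `gamma_sd` is chosen so that a
#' relaxed instrument threshold (p < 1e-5) yields a realistic number of
#' instruments with per-SNP F comfortably above 10 at those sample sizes.
#'
#' The per-SNP generative model: minor-allele frequency
#' `maf_j ~ Uniform(maf_range)`; true instrument effect
#' `gamma_j ~ Normal(0, gamma_sd^2)`; for a trait with sample size n the
#' summary-statistic SE is `1 / sqrt(n * 2 * maf_j * (1 - maf_j))`
#' (standardized-trait approximation). True mediator effects are
#' `delta_j = beta1 * gamma_j` and true outcome effects
#' `theta_j = beta_dir * gamma_j + beta2 * delta_j`, so the total effect is
#' `beta_all = beta_dir + beta1 * beta2`. A fraction `frac_invalid` of
#' SNPs violate the exclusion restriction with direct outcome effects
#' `alpha_j ~ Normal(pleiotropy_mean, pleiotropy_sd^2)`, applied on the
#' exposure-increasing allele (directional when the mean is nonzero; the
#' magnitude is independent of instrument strength, the InSIDE condition). `n_outliers` SNPs get their outcome
#' effect shifted by `outlier_shift` outcome SEs. A fraction
#' `frac_palindromic` of SNPs receive A/T or C/G allele pairs. When
#' `n_med_snps > 0`, that many additional SNPs instrument the mediator
#' directly (effect `~ Normal(0, gamma_sd^2)` on the mediator, times
#' `beta2` on the outcome, none on the exposure) so the mediator-on-outcome
#' step of two-step mediation has its own instruments.
#'
#' @param n_snps exposure-instrument candidate SNPs.
#' @param n_med_snps mediator-specific instrument SNPs (default equal to
#'   `n_snps`).
#' @param n_exp,n_med,n_out GWAS sample sizes for the three traits.
#' @param maf_range minor-allele frequency range, within (0, 0.5].
#' @param gamma_sd SD of true instrument effects (instrument strength).
#' @param beta1 exposure-on-mediator causal effect.
#' @param beta2 mediator-on-outcome causal effect.
#' @param beta_dir direct exposure-on-outcome effect (not via mediator).
#' @param pleiotropy_mean,pleiotropy_sd distribution of direct SNP-outcome
#'   effects for invalid instruments.
#' @param frac_invalid fraction of exposure SNPs that are invalid.
#' @param n_outliers number of gross outlier SNPs.
#' @param outlier_shift outlier displacement in outcome-SE units.
#' @param frac_palindromic fraction of SNPs given palindromic allele pairs.
#' @param seed integer seed recorded in the truth object.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 30, n_med_snps = n_snps,
                       n_exp = 5959, n_med = 8299, n_out = 368519,
                       maf_range = c(0.05, 0.5), gamma_sd = 0.15,
                       beta1 = 0, beta2 = 0, beta_dir = 0,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       frac_invalid = 0, n_outliers = 0, outlier_shift = 0,
                       frac_palindromic = 0, seed = 1) {
  stopifnot(n_snps >= 1, n_med_snps >= 0,
            n_exp >= 100, n_med >= 100, n_out >= 100,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            frac_invalid >= 0, frac_invalid <= 1,
            frac_palindromic >= 0, frac_palindromic <= 1,
            n_outliers >= 0, n_outliers <= n_snps)
  structure(as.list(environment()), class = "sim_config")
}

#' Named simulation scenarios
#'
#' Presets covering the situations a two-sample MR pipeline must handle:
#' \describe{
#'   \item{null}{no causal effects anywhere (type-I error calibration);
#'     30 SNPs.}
#'   \item{mediation}{beta1 = 0.4, beta2 = 0.3, beta_dir = 0.1 (true
#'     proportion mediated 0.12/0.22), 80 SNPs, n = 50000 per trait.}
#'   \item{pleiotropy}{directional pleiotropy: every SNP invalid with mean
#'     direct outcome effect 0.05; 50 SNPs.}
#'   \item{invalid40}{causal effect 0.2 with 40% invalid instruments
#'     (directional pleiotropy 0.1) — weighted-median territory.}
#'   \item{outlier}{causal effect 0.2 plus one SNP displaced by 10 outcome
#'     SEs — MR-PRESSO territory; 30 SNPs, n = 50000 per trait so the
#'     displacement is a genuine 10-SD anomaly on the residual scale
#'     (exposure noise does not dominate).}
#'   \item{reverse}{the "outcome" causes the "exposure": to be analysed
#'     with roles swapped.}
#' }
#'
#' @param name scenario name.
#' @param seed seed stored in the config.
#' @param ... overrides passed to [sim_config].
#' @return a `sim_config`.
#' @export
sim_scenario <- function(name = c("null", "mediation", "pleiotropy",
                                  "invalid40", "outlier", "reverse"),
                         seed = 1, ...) {
  name <- match.arg(name)
  args <- switch(name,
    null = list(n_snps = 30),
    mediation = list(n_snps = 80, n_med_snps = 80, beta1 = 0.4, beta2 = 0.3,
                     beta_dir = 0.1, n_exp = 50000, n_med = 50000,
                     n_out = 50000),
    pleiotropy = list(n_snps = 50, beta_dir = 0, frac_invalid = 1,
                      pleiotropy_mean = 0.05, pleiotropy_sd = 0.01),
    invalid40 = list(n_snps = 50, beta_dir = 0.2, frac_invalid = 0.4,
                     pleiotropy_mean = 0.1, pleiotropy_sd = 0.02),
    outlier = list(n_snps = 30, beta_dir = 0.2, n_outliers = 1,
                   outlier_shift = 10, n_exp = 50000, n_med = 50000,
                   n_out = 50000),
    reverse = list(n_snps = 30, beta_dir = 0.3))
  do.call(sim_config, utils::modifyList(args, c(list(seed = seed), list(...))))
}

#' Simulate a GWAS summary-statistics triplet with known truth
#'
#' Draws per-SNP observed effects for the exposure, mediator and outcome
#' from their asymptotic sampling distributions under the causal structure
#' in `cfg` (summary-level simulation: no individual genotypes). The three
#' studies are independent (non-overlapping samples, the two-sample MR
#' assumption) and share one effect-allele convention per SNP, with the
#' effect allele chosen at random per SNP consistently across tables.
#' Identical seeds give bit-identical output.
#'
#' @param cfg a [sim_config].
#' @return list with `exposure`, `mediator`, `outcome` ([gwas_table]s over
#'   the same SNPs) and `truth`: per-SNP data frame (`gamma`, `alpha`,
#'   `maf`, `is_invalid`, `is_outlier`, `is_med_instrument`) plus
#'   trait-level true `beta1`, `beta2`, `beta_dir`,
#'   `beta_all = beta_dir + beta1 * beta2` and `proportion` mediated.
#' @export
simulate_triplet <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_ex <- cfg$n_snps
    n_md <- cfg$n_med_snps
    m <- n_ex + n_md
    is_med <- c(rep(FALSE, n_ex), rep(TRUE, n_md))
    maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])

    gamma <- ifelse(is_med, 0, stats::rnorm(m, 0, cfg$gamma_sd))
    med_direct <- ifelse(is_med, stats::rnorm(m, 0, cfg$gamma_sd), 0)
    is_invalid <- !is_med &
      (stats::runif(m) < cfg$frac_invalid)
    alpha <- ifelse(is_invalid,
                    stats::rnorm(m, cfg$pleiotropy_mean, cfg$pleiotropy_sd), 0)
    is_outlier <- rep(FALSE, m)
    if (cfg$n_outliers > 0) {
      is_outlier[sample(which(!is_med), cfg$n_outliers)] <- TRUE
    }

    delta <- cfg$beta1 * gamma + med_direct              # true mediator effects
    # pleiotropy is directional relative to the exposure-increasing allele
    # (the InSIDE-style construction): align alpha with the sign of gamma
    orient <- ifelse(gamma < 0, -1, 1)
    theta <- cfg$beta_dir * gamma + cfg$beta2 * delta + orient * alpha

    se_for <- function(n) 1 / sqrt(n * 2 * maf * (1 - maf))
    se_exp <- se_for(cfg$n_exp)
    se_med <- se_for(cfg$n_med)
    se_out <- se_for(cfg$n_out)
    theta <- theta + ifelse(is_outlier, cfg$outlier_shift * se_out, 0)

    b_exp <- stats::rnorm(m, gamma, se_exp)
    b_med <- stats::rnorm(m, delta, se_med)
    b_out <- stats::rnorm(m, theta, se_out)

    # allele pairs: palindromic fraction gets A/T or C/G
    pal <- stats::runif(m) < cfg$frac_palindromic
    pair_pal <- list(c("A", "T"), c("C", "G"))
    pair_reg <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    alleles <- t(vapply(seq_len(m), function(j) {
      p <- if (pal[j]) pair_pal[[sample.int(2, 1)]] else
        pair_reg[[sample.int(4, 1)]]
      if (stats::runif(1) < 0.5) p else rev(p)  # random effect-allele choice
    }, character(2)))

    snp_id <- sprintf("rs%06d", seq_len(m))
    chrom <- as.character(rep_len(1:22, m))
    pos <- 1000000L + 2000000L * seq_len(m)  # far apart: no implicit LD

    mk <- function(beta, se, trait_id, n, type) {
      gwas_table(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                            effect_allele = alleles[, 1],
                            other_allele = alleles[, 2],
                            eaf = maf, beta = beta, se = se,
                            pval = pval_normal(beta, se), n = n,
                            stringsAsFactors = FALSE),
                 trait_id = trait_id, trait_type = type)
    }
    truth <- data.frame(snp_id = snp_id, gamma = gamma, alpha = alpha,
                        maf = maf, is_invalid = is_invalid,
                        is_outlier = is_outlier, is_med_instrument = is_med,
                        stringsAsFactors = FALSE)
    beta_all <- cfg$beta_dir + cfg$beta1 * cfg$beta2
    list(exposure = mk(b_exp, se_exp, "exposure", cfg$n_exp, "continuous"),
         mediator = mk(b_med, se_med, "mediator", cfg$n_med, "continuous"),
         outcome = mk(b_out, se_out, "outcome", cfg$n_out, "binary"),
         truth = list(per_snp = truth, beta1 = cfg$beta1, beta2 = cfg$beta2,
                      beta_dir = cfg$beta_dir, beta_all = beta_all,
                      proportion = if (beta_all != 0)
                        cfg$beta1 * cfg$beta2 / beta_all else NA_real_,
                      seed = cfg$seed))
  })
}

#' Build a block LD structure for clumping tests
#'
#' Groups the first `n_snps` simulated SNPs into consecutive blocks of
#' `block_size`, assigns within-block pairwise r-squared
#' `within_block_r2` (between blocks 0), and returns positions placing
#' each block inside a clumping window on one chromosome per block.
#'
#' @param snp_ids character vector of SNP IDs to group.
#' @param block_size SNPs per block (>= 1).
#' @param within_block_r2 r-squared between SNPs of the same block.
#' @return list with `ld` (an `ld_info`), `chrom` and `pos` vectors aligned
#'   with `snp_ids` (blocks 100 kb wide, 50 Mb apart).
#' @export
make_ld_panel <- function(snp_ids, block_size = 4, within_block_r2 = 0.9) {
  stopifnot(block_size >= 1)
  m <- length(snp_ids)
  block <- (seq_len(m) - 1L) %/% block_size
  within <- (seq_len(m) - 1L) %% block_size
  pairs <- list()
  for (b in unique(block)) {
    ids <- snp_ids[block == b]
    if (length(ids) >= 2) {
      idx <- utils::combn(length(ids), 2)
      pairs[[length(pairs) + 1]] <-
        data.frame(snp_a = ids[idx[1, ]], snp_b = ids[idx[2, ]],
                   r2 = within_block_r2, stringsAsFactors = FALSE)
    }
  }
  ld <- if (length(pairs)) ld_pairs(do.call(rbind, pairs)) else ld_pairs()
  list(ld = ld,
       chrom = as.character(rep_len(1:22, length(unique(block))))[block + 1L],
       pos = 1000000L + block * 50000000L + within * 10000L)
}
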