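#' Cochran's Q heterogeneity test
#'
#' Q = sum of `w_j (theta_j - theta_ivw)^2` over per-SNP Wald ratios, with
#' the fixed-effect IVW estimate as center (the standard definition, even
#' when the headline IVW is random-effects). Under homogeneity Q is
#' chi-square with nsnp - 1 df.
#'
#' @param ratios data frame from [wald_ratio]; needs at least 2 rows.
#' @return list with `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(ratios) {
  n <- nrow(ratios)
  if (n < 2) stop("Cochran's Q needs at least 2 instruments")
  w <- ratios$weight
  center <- sum(w * ratios$wald) / sum(w)
  q <- sum(w * (ratios$wald - center)^2)
  list(q_stat = q, q_df = n - 1L,
       q_pval = stats::pchisq(q, df = n - 1, lower.tail = FALSE))
}

#' Leave-one-out analysis
#'
#' Re-estimates the IVW effect with each SNP removed in turn. A row is
#' flagged influential when dropping its SNP flips the sign of the estimate
#' or moves its p-value across `alpha` relative to the full-set IVW.
#'
#' @param pairs a `harmonized_set`; needs at least 2 variants.
#' @param ivw_mode passed to [mr_ivw].
#' @param alpha significance level used for the flag (default 0.05).
#' @return data frame with one row per left-out SNP: `left_out_snp`,
#'   `beta`, `se`, `pval`, `flag`; the full-set IVW is attached as
#'   attribute `full`.
#' @export
leave_one_out <- function(pairs, ivw_mode = "multiplicative_random",
                          alpha = 0.05) {
  n <- nrow(pairs)
  if (n < 2) stop("leave-one-out needs at least 2 instruments")
  ratios <- ratios_of(pairs)
  full <- mr_ivw(ratios, mode = ivw_mode)
  rows <- lapply(seq_len(n), function(j) {
    fit <- mr_ivw(ratios[-j, , drop = FALSE], mode = ivw_mode)
    data.frame(left_out_snp = pairs$snp_id[j], beta = fit$beta, se = fit$se,
               pval = fit$pval, stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  loo$flag <- sign(loo$beta) != sign(full$beta) |
    ((loo$pval >= alpha) != (full$pval >= alpha))
  attr(loo, "full") <- full
  loo
}

#' MR-PRESSO global test, outlier detection and correction
#'
#' Pleiotropy Residual Sum and Outlier test. The observed global statistic
#' is `RSS = sum_j w_j (beta_out_j - b_(-j) * beta_exp_j)^2` with
#' `w_j = 1 / se_out_j^2` and `b_(-j)` the leave-one-out fixed-effect IVW
#' slope. Its null distribution is simulated: in each of `n_sim` seeded
#' replicates, `beta_exp* ~ Normal(beta_exp_j, se_exp_j)` and
#' `beta_out* ~ Normal(b_(-j) beta_exp_j, se_out_j)`, and the RSS is
#' recomputed. The global p-value uses the add-one estimator
#' `(1 + #\{RSS* >= RSS\}) / (n_sim + 1)`, so its floor is `1/(n_sim+1)`.
#' Per-SNP outlier p-values compare each observed weighted squared residual
#' with its own simulated distribution, Bonferroni-corrected over nsnp
#' against `outlier_alpha`. When outliers are found, the outlier-corrected
#' IVW on the remaining SNPs is reported together with a distortion test:
#' the observed relative change `(corrected - original)/original` is
#' compared two-sidedly with its distribution under simulated null data
#' with the same number of randomly chosen SNPs removed.
#'
#' @param pairs a `harmonized_set`; needs at least 4 variants.
#' @param n_sim number of null simulations (default 1000; fewer than 100
#'   triggers a warning).
#' @param seed integer seed (RNG state restored afterwards).
#' @param outlier_alpha familywise level for outlier calls.
#' @return list of class `mr_presso`: `rss_obs`, `global_pval`, `n_sim`,
#'   `seed`, `outlier_snps` (character), `outlier_pvals` (named, Bonferroni-
#'   adjusted), `beta_corrected` and `distortion_pval` (`NULL` when no
#'   outlier is removed).
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  n <- nrow(pairs)
  if (n < 4) stop("MR-PRESSO needs at least 4 instruments")
  if (n_sim < 100) warning("n_sim < 100 gives a coarse null distribution")
  bx <- pairs$beta_exp; sx <- pairs$se_exp
  by <- pairs$beta_out; sy <- pairs$se_out
  w_ratio <- (sy / abs(bx))^-2  # IVW weights on the ratio scale
  theta <- by / bx
  # leave-one-out fixed-effect IVW slopes
  sw <- sum(w_ratio); swt <- sum(w_ratio * theta)
  b_loo <- (swt - w_ratio * theta) / (sw - w_ratio)
  w_out <- sy^-2
  res_obs <- w_out * (by - b_loo * bx)^2
  rss_obs <- sum(res_obs)

  sims <- with_seed(seed, {
    bx_star <- matrix(stats::rnorm(n_sim * n, mean = rep(bx, each = n_sim),
                                   sd = rep(sx, each = n_sim)), nrow = n_sim)
    by_star <- matrix(stats::rnorm(n_sim * n,
                                   mean = rep(b_loo * bx, each = n_sim),
                                   sd = rep(sy, each = n_sim)), nrow = n_sim)
    # per-replicate leave-one-out slopes on the simulated data
    theta_s <- by_star / bx_star
    w_s <- (rep(sy, each = n_sim) / abs(bx_star))^2
    w_s <- 1 / w_s
    sw_s <- rowSums(w_s); swt_s <- rowSums(w_s * theta_s)
    b_loo_s <- (swt_s - w_s * theta_s) / (sw_s - w_s)
    res_s <- rep(w_out, each = n_sim) * (by_star - b_loo_s * bx_star)^2
    dim(res_s) <- c(n_sim, n)
    res_s
  })
  rss_sim <- rowSums(sims)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  # per-SNP: observed weighted residual vs its simulated null distribution
  p_snp <- vapply(seq_len(n), function(j) {
    (1 + sum(sims[, j] >= res_obs[j])) / (n_sim + 1)
  }, numeric(1))
  p_adj <- pmin(1, p_snp * n)
  names(p_adj) <- pairs$snp_id
  outliers <- pairs$snp_id[p_adj < outlier_alpha]

  beta_corrected <- NULL
  distortion_pval <- NULL
  if (length(outliers) > 0 && n - length(outliers) >= 2) {
    keep <- !(pairs$snp_id %in% outliers)
    ratios <- ratios_of(pairs)
    orig <- mr_ivw(ratios, mode = "fixed")$beta
    beta_corrected <- mr_ivw(ratios[keep, , drop = FALSE], mode = "fixed")$beta
    d_obs <- (beta_corrected - orig) / orig
    n_out <- length(outliers)
    d_sim <- with_seed(seed + 1L, {
      vapply(seq_len(min(n_sim, 500)), function(b) {
        bx_s <- stats::rnorm(n, bx, sx)
        by_s <- stats::rnorm(n, b_loo * bx, sy)
        th <- by_s / bx_s; wv <- (sy / abs(bx_s))^-2
        drop <- sample.int(n, n_out)
        full <- sum(wv * th) / sum(wv)
        part <- sum((wv * th)[-drop]) / sum(wv[-drop])
        (part - full) / full
      }, numeric(1))
    })
    distortion_pval <- (1 + sum(abs(d_sim) >= abs(d_obs))) /
      (length(d_sim) + 1)
  }
  structure(list(rss_obs = rss_obs, global_pval = global_pval,
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 outlier_snps = outliers, outlier_pvals = p_adj,
                 beta_corrected = beta_corrected,
                 distortion_pval = distortion_pval),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.3f, p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_pval, x$n_sim))
  if (length(x$outlier_snps) > 0) {
    cat("  outliers:", paste(x$outlier_snps, collapse = ", "), "\n")
    cat(sprintf("  outlier-corrected IVW beta = %.4f (distortion p = %.3g)\n",
                x$beta_corrected, x$distortion_pval))
  } else cat("  no outliers detected\n")
  invisible(x)
}

#' Full sensitivity report for one exposure-outcome pair
#'
#' Bundles Cochran's Q, the MR-Egger intercept test, leave-one-out IVW and
#' (when at least 4 instruments are available and `n_sim > 0`) MR-PRESSO.
#'
#' @param pairs a `harmonized_set`; needs at least 2 variants.
#' @param n_sim MR-PRESSO simulations; 0 skips PRESSO.
#' @param seed seed for MR-PRESSO.
#' @param outlier_alpha familywise level for PRESSO outlier calls.
#' @return list of class `sensitivity_report`: `q_stat`, `q_df`, `q_pval`,
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_pval` (`NA`
#'   with < 3 SNPs), `loo` (table from [leave_one_out]), `presso`
#'   (`NULL` if skipped).
#' @export
sensitivity_report <- function(pairs, n_sim = 1000, seed = 1,
                               outlier_alpha = 0.05) {
  q <- cochran_q(ratios_of(pairs))
  egger <- if (nrow(pairs) >= 3) mr_egger(pairs) else NULL
  presso <- if (n_sim > 0 && nrow(pairs) >= 4) {
    mr_presso(pairs, n_sim = n_sim, seed = seed, outlier_alpha = outlier_alpha)
  } else NULL
  structure(list(q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval,
                 egger_intercept = egger$intercept %||% NA_real_,
                 egger_intercept_se = egger$intercept_se %||% NA_real_,
                 egger_intercept_pval = egger$intercept_pval %||% NA_real_,
                 loo = leave_one_out(pairs),
                 presso = presso),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df (p = %.3g)\n",
              x$q_stat, x$q_df, x$q_pval))
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("MR-Egger intercept = %.4f (se %.4f, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_pval))
  }
  cat(sprintf("Leave-one-out: %d rows, %d flagged\n",
              nrow(x$loo), sum(x$loo$flag)))
  if (!is.null(x$presso)) print(x$presso)
  invisible(x)
}
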