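#' Per-SNP Wald ratio estimates
#'
#' The building block of summary-data MR: for each variant, the causal
#' effect is estimated as the ratio of the outcome effect to the exposure
#' effect, with first-order standard error `se_out / |beta_exp|`. The
#' inverse-variance weight `1 / wald_se^2` is attached.
#'
#' @param beta_exp,se_exp exposure effect estimates and SEs.
#' @param beta_out,se_out outcome effect estimates and SEs.
#' @return data frame with columns `wald`, `wald_se`, `weight`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) stop("degenerate instrument: beta_exp = 0")
  wald <- beta_out / beta_exp
  wald_se <- se_out / abs(beta_exp)
  data.frame(wald = wald, wald_se = wald_se, weight = wald_se^-2)
}

ratios_of <- function(pairs) {
  wald_ratio(pairs$beta_exp, pairs$se_exp, pairs$beta_out, pairs$se_out)
}

mr_result <- function(method, nsnp, beta, se, pval) {
  ci <- to_odds_ratio(beta, se)
  data.frame(method = method, nsnp = as.integer(nsnp), beta = beta, se = se,
             pval = pval, or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimate
#'
#' The IVW estimate is the weighted mean of Wald ratios with weights
#' `1 / wald_se^2`. The default multiplicative random-effects model inflates
#' the fixed-effect SE by `sqrt(Q / (nsnp - 1))`, floored at 1, so it
#' reduces to the fixed-effect model under homogeneity (Q <= df). The
#' p-value is two-sided normal.
#'
#' @param ratios data frame from [wald_ratio].
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return one-row data frame with `method`, `nsnp`, `beta`, `se`, `pval`,
#'   `or`, `ci_low`, `ci_high`.
#' @export
mr_ivw <- function(ratios, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  n <- nrow(ratios)
  if (n < 1) stop("cannot estimate from an empty instrument set")
  w <- ratios$weight
  beta <- sum(w * ratios$wald) / sum(w)
  se <- sqrt(1 / sum(w))
  if (mode == "multiplicative_random" && n >= 2) {
    q <- sum(w * (ratios$wald - beta)^2)
    se <- se * max(1, sqrt(q / (n - 1)))
  }
  mr_result("ivw", n, beta, se, pval_normal(beta, se))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with an intercept, weights `1 / se_out^2`, after orienting every variant
#' so its exposure effect is non-negative (negating both effects where
#' needed, as the estimator's interpretation requires). A nonzero intercept
#' indicates directional horizontal pleiotropy; the slope is the
#' pleiotropy-adjusted causal estimate. Coefficient SEs use the residual
#' variance inflation factor floored at 1; p-values come from the t
#' distribution with nsnp - 2 df.
#'
#' @param pairs a `harmonized_set` (or any data frame with `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`); needs at least 3 variants.
#' @return list with `slope` (one-row data frame as from [mr_ivw], method
#'   `"egger"`), `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(pairs$beta_exp)
  flip[flip == 0] <- 1
  x <- pairs$beta_exp * flip
  y <- pairs$beta_out * flip
  w <- pairs$se_out^-2
  fit <- stats::lm(y ~ x, weights = w)
  sigma <- sqrt(sum(w * stats::residuals(fit)^2) / (n - 2))
  # Base (sigma-free) coefficient SEs from the weighted design, scaled by
  # the residual SD floored at 1 — robust to an exactly-fitting line.
  xtwx_inv <- solve(crossprod(cbind(1, x) * sqrt(w)))
  se_base <- sqrt(diag(xtwx_inv))
  se_int <- se_base[1] * max(1, sigma)
  se_slope <- se_base[2] * max(1, sigma)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  list(slope = mr_result("egger", n, slope, se_slope,
                         2 * stats::pt(-abs(slope / se_slope), df = n - 2)),
       intercept = intercept,
       intercept_se = se_int,
       intercept_pval = 2 * stats::pt(-abs(intercept / se_int), df = n - 2))
}

#' Weighted median estimate
#'
#' The weighted median of the Wald-ratio distribution: ratios are ordered,
#' standardized cumulative weights `s_j = (sum_{i<=j} w_i - w_j/2) / sum(w)`
#' computed, and the estimate is the linear interpolation of the ordered
#' ratios at s = 0.5. Consistent when at least half the total weight comes
#' from valid instruments. The SE is a seeded parametric bootstrap: each
#' ratio is resampled from Normal(wald_j, wald_se_j) `n_boot` times and the
#' SD of the re-estimates taken.
#'
#' @param ratios data frame from [wald_ratio]; needs at least 2 rows.
#' @param n_boot bootstrap replicates for the SE (default 1000).
#' @param seed integer seed for the bootstrap (RNG state is restored).
#' @return one-row data frame as from [mr_ivw], method `"weighted_median"`.
#' @export
mr_weighted_median <- function(ratios, n_boot = 1000, seed = 1) {
  n <- nrow(ratios)
  if (n < 2) stop("weighted median needs at least 2 instruments")
  est <- weighted_median_point(ratios$wald, ratios$weight)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      weighted_median_point(stats::rnorm(n, ratios$wald, ratios$wald_se),
                            ratios$weight)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_result("weighted_median", n, est, se, pval_normal(est, se))
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(theta[1])
  if (s[length(s)] <= 0.5) return(theta[length(s)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Log-scale effect to odds ratio with 95% confidence interval
#'
#' `or = exp(beta)`, `ci = exp(beta -/+ 1.959964 * se)`; the critical value
#' is fixed so the interval is bit-stable. The geometric mean of the CI
#' bounds equals the OR by construction.
#'
#' @param beta log odds ratio estimate.
#' @param se its standard error (> 0).
#' @return data frame with columns `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(beta, se) {
  stopifnot(all(se > 0))
  data.frame(or = exp(beta),
             ci_low = exp(beta - Z95 * se),
             ci_high = exp(beta + Z95 * se))
}
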