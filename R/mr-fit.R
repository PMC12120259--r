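#' Fit two-sample Mendelian randomization estimators
#'
#' The central fitting function: given harmonized exposure/outcome effect
#' pairs, computes the requested causal-effect estimators and returns them
#' in a single model object. The inverse-variance weighted (IVW) estimate
#' is the primary result; MR-Egger and the weighted median serve as
#' pleiotropy-robust secondary estimators. With a single variant the IVW
#' reduces to that variant's Wald ratio.
#'
#' @param pairs a `harmonized_set` from [harmonize] or [harmonized_pairs].
#' @param methods which estimators to run; estimators whose minimum
#'   instrument count exceeds `nrow(pairs)` are skipped with a note rather
#'   than an error when others remain.
#' @param ivw_mode passed to [mr_ivw].
#' @param n_boot,seed bootstrap controls for [mr_weighted_median].
#' @return An object of class `mr_fit` with components `results` (one row
#'   per estimator: `method`, `nsnp`, `beta`, `se`, `pval`, `or`, `ci_low`,
#'   `ci_high`), `egger_intercept` (estimate, SE, p — `NULL` if Egger not
#'   run), `pairs`, `exposure_id`, `outcome_id`, `z_crit`, `seed`.
#' @seealso [sensitivity_report] for diagnostics, [mr_mediate] for
#'   two-step mediation.
#' @examples
#' h <- harmonized_pairs(beta_exp = c(0.12, 0.15, 0.10, 0.20),
#'                       se_exp = rep(0.02, 4),
#'                       beta_out = c(0.036, 0.046, 0.031, 0.059),
#'                       se_out = rep(0.01, 4))
#' fit <- mr_fit(h)
#' coef(fit)
#' @export
mr_fit <- function(pairs, methods = c("ivw", "egger", "weighted_median"),
                   ivw_mode = "multiplicative_random", n_boot = 1000,
                   seed = 1) {
  methods <- match.arg(methods, c("ivw", "egger", "weighted_median",
                                  "wald_ratio"), several.ok = TRUE)
  n <- nrow(pairs)
  if (n == 0) stop("cannot fit on an empty harmonized set")
  ratios <- ratios_of(pairs)
  results <- list()
  egger_int <- NULL
  for (m in methods) {
    if (m == "ivw") {
      results[[m]] <- mr_ivw(ratios, mode = ivw_mode)
    } else if (m == "wald_ratio" && n == 1) {
      r <- mr_ivw(ratios, mode = "fixed")
      r$method <- "wald_ratio"
      results[[m]] <- r
    } else if (m == "egger" && n >= 3) {
      e <- mr_egger(pairs)
      results[[m]] <- e$slope
      egger_int <- e[c("intercept", "intercept_se", "intercept_pval")]
    } else if (m == "weighted_median" && n >= 2) {
      results[[m]] <- mr_weighted_median(ratios, n_boot = n_boot, seed = seed)
    }
  }
  if (length(results) == 0) stop("no requested estimator is applicable to ",
                                 n, " instrument(s)")
  structure(list(results = do.call(rbind, c(results, make.row.names = FALSE)),
                 egger_intercept = egger_int,
                 pairs = pairs,
                 exposure_id = attr(pairs, "exposure_id") %||% "exposure",
                 outcome_id = attr(pairs, "outcome_id") %||% "outcome",
                 z_crit = Z95,
                 seed = seed),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d SNPs)\n",
              x$exposure_id, x$outcome_id, nrow(x$pairs)))
  df <- x$results
  out <- data.frame(method = df$method, nsnp = df$nsnp,
                    beta = signif(df$beta, digits),
                    se = signif(df$se, digits),
                    OR = sprintf("%.2f", df$or),
                    `95% CI` = sprintf("%.2f-%.2f", df$ci_low, df$ci_high),
                    p = signif(df$pval, digits), check.names = FALSE)
  print(out, row.names = FALSE)
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("MR-Egger intercept: %.4f (se %.4f, p = %.3g)\n",
                x$egger_intercept$intercept, x$egger_intercept$intercept_se,
                x$egger_intercept$intercept_pval))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  df <- object$results
  out <- cbind(df$beta - z * df$se, df$beta + z * df$se)
  dimnames(out) <- list(df$method,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  out
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object,
                 sensitivity = tryCatch(
                   sensitivity_report(object$pairs, n_sim = 0),
                   error = function(e) NULL)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  s <- x$sensitivity
  if (!is.null(s)) {
    cat(sprintf("Cochran's Q = %.3f on %d df (p = %.3g)\n",
                s$q_stat, s$q_df, s$q_pval))
    if (!is.null(s$loo)) {
      rng <- range(s$loo$beta)
      cat(sprintf("Leave-one-out IVW range: [%.4f, %.4f]%s\n", rng[1], rng[2],
                  if (any(s$loo$flag)) " (influential SNP flagged)" else ""))
    }
  }
  invisible(x)
}

#' Scatter plot of a fitted MR model
#'
#' Plots outcome effects against exposure effects (oriented to non-negative
#' exposure effects) with one fitted line per estimator: through the origin
#' for IVW and the weighted median, with its intercept for MR-Egger.
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot].
#' @export
plot.mr_fit <- function(x, ...) {
  flip <- sign(x$pairs$beta_exp); flip[flip == 0] <- 1
  bx <- x$pairs$beta_exp * flip
  by <- x$pairs$beta_out * flip
  graphics::plot(bx, by, xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 main = sprintf("%s -> %s", x$exposure_id, x$outcome_id), ...)
  graphics::segments(bx, by - Z95 * x$pairs$se_out,
                     bx, by + Z95 * x$pairs$se_out, col = "grey70")
  graphics::abline(h = 0, col = "grey85", lty = 3)
  cols <- c(ivw = "black", egger = "firebrick", weighted_median = "steelblue",
            wald_ratio = "black")
  for (i in seq_len(nrow(x$results))) {
    m <- x$results$method[i]
    a <- if (m == "egger") x$egger_intercept$intercept else 0
    graphics::abline(a = a, b = x$results$beta[i], col = cols[[m]],
                     lty = which(names(cols) == m))
  }
  graphics::legend("topleft", legend = x$results$method,
                   col = cols[x$results$method],
                   lty = match(x$results$method, names(cols)), bty = "n")
  invisible(x)
}

#' Residuals of a fitted MR model
#'
#' Weighted residuals of outcome effects from the chosen estimator's fitted
#' line, in outcome-SE units: `(beta_out - a - b * beta_exp) / se_out`.
#'
#' @param object an `mr_fit`.
#' @param method which estimator's line to use (default the first fitted).
#' @param ... unused.
#' @export
residuals.mr_fit <- function(object, method = object$results$method[1], ...) {
  i <- match(method, object$results$method)
  if (is.na(i)) stop("method not fitted: ", method)
  a <- if (method == "egger") object$egger_intercept$intercept else 0
  flip <- sign(object$pairs$beta_exp); flip[flip == 0] <- 1
  bx <- object$pairs$beta_exp * flip
  by <- object$pairs$beta_out * flip
  (by - a - object$results$beta[i] * bx) / object$pairs$se_out
}
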