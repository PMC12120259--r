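#' Two-step mediation decomposition
#'
#' Decomposes the total causal effect of an exposure on the outcome
#' (`beta_all`) into the indirect path through a mediator,
#' `beta_indir = beta1 * beta2` (exposure-to-mediator times
#' mediator-to-outcome), and the direct remainder
#' `beta_dir = beta_all - beta1 * beta2`. The proportion mediated is
#' `beta_indir / beta_all`. The indirect effect's SE uses the product
#' delta method, `sqrt(beta1^2 se2^2 + beta2^2 se1^2)`, and its 95% CI is
#' `beta_indir -/+ 1.959964 * se_indir`. Rows where the indirect and total
#' effects disagree in sign, or where the proportion falls outside [0, 1],
#' are flagged rather than suppressed.
#'
#' Either supply `beta1`/`beta2` (with `beta_indir` computed), or supply
#' `beta_indir` directly when only the product is known (as in published
#' tables); in that case the delta-method SE is unavailable.
#'
#' @param beta_all total effect, exposure on outcome (log odds for a binary
#'   outcome).
#' @param beta1 exposure-on-mediator effect.
#' @param beta2 mediator-on-outcome effect.
#' @param se_all,se1,se2 standard errors (optional; needed for `se_indir`).
#' @param beta_indir the product `beta1 * beta2`, if given directly.
#' @param exposure_id,mediator_id,outcome_id labels.
#' @return An object of class `mr_mediation`: one-row data frame with
#'   `beta_all`, `beta1`, `beta2`, `beta_indir`, `beta_dir`, `proportion`
#'   (as a fraction), `proportion_pct` (percentage rounded half-up to 2
#'   decimals), `se_indir`, `ci_indir_low`, `ci_indir_high`, `flags`.
#' @examples
#' mr_mediate(beta_all = 0.25, beta1 = 0.5, beta2 = 0.2)  # 40% mediated
#' @export
mr_mediate <- function(beta_all, beta1 = NA_real_, beta2 = NA_real_,
                       se_all = NA_real_, se1 = NA_real_, se2 = NA_real_,
                       beta_indir = beta1 * beta2,
                       exposure_id = "exposure", mediator_id = "mediator",
                       outcome_id = "outcome") {
  stopifnot(length(beta_all) == 1)
  beta_dir <- beta_all - beta_indir
  proportion <- if (beta_all != 0) beta_indir / beta_all else NA_real_
  se_indir <- if (!is.na(se1) && !is.na(se2)) {
    sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  } else NA_real_
  flags <- character()
  if (beta_all == 0) flags <- c(flags, "proportion_undefined")
  if (!is.na(beta_indir) && beta_indir != 0 &&
      sign(beta_indir) != sign(beta_all)) {
    flags <- c(flags, "inconsistent_sign")
  }
  if (!is.na(proportion) && (proportion < 0 || proportion > 1)) {
    flags <- c(flags, "proportion_outside_unit")
  }
  structure(data.frame(
    exposure_id = exposure_id, mediator_id = mediator_id,
    outcome_id = outcome_id,
    beta_all = beta_all, beta1 = beta1, beta2 = beta2,
    beta_indir = beta_indir, beta_dir = beta_dir,
    proportion = proportion,
    proportion_pct = round_half_up(100 * proportion, 2),
    se_indir = se_indir,
    ci_indir_low = beta_indir - Z95 * se_indir,
    ci_indir_high = beta_indir + Z95 * se_indir,
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE),
    class = c("mr_mediation", "data.frame"))
}

# round-half-up (not banker's rounding) to match tabular percentage style
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.mr_mediation <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%s -> %s -> %s\n", x$exposure_id[i], x$mediator_id[i],
                x$outcome_id[i]))
    cat(sprintf("  beta_all = %.7g; indirect = %.7g; direct = %.7g; proportion mediated = %.2f%%\n",
                x$beta_all[i], x$beta_indir[i], x$beta_dir[i],
                x$proportion_pct[i]))
    if (nzchar(x$flags[i])) cat("  flags:", x$flags[i], "\n")
  }
  invisible(x)
}

#' Screen exposure-mediator pairs for mediation
#'
#' Emits a mediation decomposition for every (exposure, mediator) pair
#' where all three links are nominally significant: exposure-on-mediator
#' (`step1`), mediator-on-outcome (`step2`) and exposure-on-outcome
#' (`total`) IVW p-values all below `alpha`. Non-qualifying pairs are
#' recorded in the attached `skip_log` with the failing step.
#'
#' @param step1 data frame of exposure-on-mediator IVW results: columns
#'   `exposure_id`, `mediator_id`, `beta`, `se`, `pval`.
#' @param step2 data frame of mediator-on-outcome IVW results: columns
#'   `mediator_id`, `outcome_id`, `beta`, `se`, `pval`.
#' @param total data frame of exposure-on-outcome IVW results: columns
#'   `exposure_id`, `outcome_id`, `beta`, `se`, `pval`.
#' @param alpha nominal gate (default 0.05).
#' @return An `mr_mediation` table (0 or more rows) with attribute
#'   `skip_log`: data frame of skipped pairs and reasons.
#' @export
mediation_screen <- function(step1, step2, total, alpha = 0.05) {
  need <- function(df, cols, nm) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(nm, " table lacks column(s): ",
                           paste(miss, collapse = ", "))
  }
  need(step1, c("exposure_id", "mediator_id", "beta", "se", "pval"), "step1")
  need(step2, c("mediator_id", "outcome_id", "beta", "se", "pval"), "step2")
  need(total, c("exposure_id", "outcome_id", "beta", "se", "pval"), "total")

  out <- list(); skips <- list()
  for (i in seq_len(nrow(step1))) {
    exp_id <- step1$exposure_id[i]; med_id <- step1$mediator_id[i]
    j <- which(step2$mediator_id == med_id)
    k <- which(total$exposure_id == exp_id)
    pair <- sprintf("%s|%s", exp_id, med_id)
    if (length(j) == 0 || length(k) == 0) {
      skips[[pair]] <- "missing step2 or total row"; next
    }
    j <- j[1]; k <- k[1]
    if (step1$pval[i] >= alpha) { skips[[pair]] <- "step1 not significant"; next }
    if (step2$pval[j] >= alpha) { skips[[pair]] <- "step2 not significant"; next }
    if (total$pval[k] >= alpha) { skips[[pair]] <- "total not significant"; next }
    out[[pair]] <- mr_mediate(
      beta_all = total$beta[k], beta1 = step1$beta[i], beta2 = step2$beta[j],
      se_all = total$se[k], se1 = step1$se[i], se2 = step2$se[j],
      exposure_id = exp_id, mediator_id = med_id,
      outcome_id = total$outcome_id[k])
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    mr_mediate(beta_all = 1)[0, ]
  skip_log <- data.frame(pair = names(skips) %||% character(),
                         reason = unlist(skips, use.names = FALSE) %||% character(),
                         stringsAsFactors = FALSE)
  structure(res, skip_log = skip_log,
            class = c("mr_mediation", "data.frame"))
}
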