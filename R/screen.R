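#' Screening configuration
#'
#' Thresholds for the forward/reverse screening pipeline. Defaults mirror
#' nominal-significance practice in summary-data MR screens: IVW p < 0.05
#' with direction concordance required against MR-Egger, sensitivity tests
#' (Q, Egger intercept, PRESSO global) required non-significant for a
#' "robust" verdict, and reverse-causal pairs excluded at p < 0.05.
#'
#' @param selection a [selection_config] for instrument selection.
#' @param ivw_alpha significance level for the primary IVW estimate.
#' @param require_egger_concordance must the Egger slope share IVW's sign?
#' @param require_median_concordance must the weighted median share it too?
#' @param sensitivity_alpha level above which Q / intercept / PRESSO global
#'   p-values must stay for a robust verdict.
#' @param reverse_alpha reverse-direction IVW p below this excludes a pair.
#' @param n_sim MR-PRESSO simulations per pair.
#' @param seed master seed; per-pair seeds are derived deterministically.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(selection = selection_config(), ivw_alpha = 0.05,
                          require_egger_concordance = TRUE,
                          require_median_concordance = FALSE,
                          sensitivity_alpha = 0.05, reverse_alpha = 0.05,
                          n_sim = 1000, seed = 1) {
  stopifnot(ivw_alpha > 0, ivw_alpha < 1,
            sensitivity_alpha > 0, sensitivity_alpha < 1,
            reverse_alpha > 0, reverse_alpha < 1)
  structure(list(selection = selection, ivw_alpha = ivw_alpha,
                 require_egger_concordance = require_egger_concordance,
                 require_median_concordance = require_median_concordance,
                 sensitivity_alpha = sensitivity_alpha,
                 reverse_alpha = reverse_alpha,
                 n_sim = n_sim, seed = as.integer(seed)),
            class = "screen_config")
}

# Verdict from a row's stored statistics under the config thresholds;
# kept separate so verdicts are recomputable from a screen table.
screen_verdict <- function(row, cfg) {
  if (is.na(row$nsnp) || row$nsnp == 0) return("skipped_no_instruments")
  if (is.na(row$ivw_pval) || row$ivw_pval >= cfg$ivw_alpha) {
    return("not_significant")
  }
  concordant <- TRUE
  if (cfg$require_egger_concordance && !is.na(row$egger_beta)) {
    concordant <- concordant && sign(row$egger_beta) == sign(row$ivw_beta)
  }
  if (cfg$require_median_concordance && !is.na(row$wm_beta)) {
    concordant <- concordant && sign(row$wm_beta) == sign(row$ivw_beta)
  }
  sens_ok <- all(c(row$q_pval, row$egger_intercept_pval, row$presso_pval) >
                   cfg$sensitivity_alpha, na.rm = TRUE)
  if (concordant && sens_ok) "significant_robust" else "significant_unstable"
}

screen_one <- function(exposure, outcome, ld, cfg, pair_seed) {
  row <- data.frame(exposure_id = attr(exposure, "trait_id"),
                    outcome_id = attr(outcome, "trait_id"),
                    nsnp = 0L,
                    ivw_beta = NA_real_, ivw_se = NA_real_, ivw_pval = NA_real_,
                    ivw_or = NA_real_, ivw_ci_low = NA_real_,
                    ivw_ci_high = NA_real_,
                    egger_beta = NA_real_, egger_pval = NA_real_,
                    wm_beta = NA_real_, wm_pval = NA_real_,
                    q_pval = NA_real_, egger_intercept_pval = NA_real_,
                    presso_pval = NA_real_, n_loo_flagged = NA_integer_,
                    reverse_ivw_pval = NA_real_,
                    verdict = "skipped_no_instruments",
                    stringsAsFactors = FALSE)
  iv <- select_instruments(exposure, ld, cfg$selection)
  if (nrow(iv) == 0) return(row)
  h <- harmonize(iv, outcome)
  if (nrow(h) == 0) return(row)
  fit <- mr_fit(h, seed = pair_seed)
  res <- fit$results
  row$nsnp <- nrow(h)
  ivw <- res[res$method == "ivw", ]
  row$ivw_beta <- ivw$beta; row$ivw_se <- ivw$se; row$ivw_pval <- ivw$pval
  row$ivw_or <- ivw$or; row$ivw_ci_low <- ivw$ci_low
  row$ivw_ci_high <- ivw$ci_high
  if ("egger" %in% res$method) {
    row$egger_beta <- res$beta[res$method == "egger"]
    row$egger_pval <- res$pval[res$method == "egger"]
  }
  if ("weighted_median" %in% res$method) {
    row$wm_beta <- res$beta[res$method == "weighted_median"]
    row$wm_pval <- res$pval[res$method == "weighted_median"]
  }
  if (nrow(h) >= 2) {
    sens <- sensitivity_report(h, n_sim = cfg$n_sim, seed = pair_seed)
    row$q_pval <- sens$q_pval
    row$egger_intercept_pval <- sens$egger_intercept_pval
    row$presso_pval <- if (!is.null(sens$presso)) sens$presso$global_pval else NA_real_
    row$n_loo_flagged <- sum(sens$loo$flag)
  }
  row$verdict <- screen_verdict(row, cfg)
  row
}

#' Forward MR screen across many exposures
#'
#' For each exposure: select instruments, harmonize against the outcome,
#' fit IVW / MR-Egger / weighted median, run the sensitivity suite, and
#' assign a verdict: `significant_robust` (IVW p below `ivw_alpha`,
#' direction concordant with MR-Egger, and no sensitivity alarm),
#' `significant_unstable`, `not_significant`, or `skipped_no_instruments`.
#' Deterministic given the config seed: each pair's seed is derived from
#' the master seed and the exposure's position.
#'
#' @param exposures list of [gwas_table] objects.
#' @param outcome a [gwas_table].
#' @param ld an `ld_info` or `NULL`.
#' @param cfg a [screen_config].
#' @return data frame of class `screen_table`, one row per exposure.
#' @export
run_forward_screen <- function(exposures, outcome, ld = NULL,
                               cfg = screen_config()) {
  rows <- lapply(seq_along(exposures), function(i) {
    tryCatch(
      screen_one(exposures[[i]], outcome, ld, cfg,
                 pair_seed = (cfg$seed + i) %% .Machine$integer.max),
      error = function(e) {
        data.frame(exposure_id = attr(exposures[[i]], "trait_id"),
                   outcome_id = attr(outcome, "trait_id"), nsnp = 0L,
                   ivw_beta = NA_real_, ivw_se = NA_real_, ivw_pval = NA_real_,
                   ivw_or = NA_real_, ivw_ci_low = NA_real_,
                   ivw_ci_high = NA_real_, egger_beta = NA_real_,
                   egger_pval = NA_real_, wm_beta = NA_real_,
                   wm_pval = NA_real_, q_pval = NA_real_,
                   egger_intercept_pval = NA_real_, presso_pval = NA_real_,
                   n_loo_flagged = NA_integer_, reverse_ivw_pval = NA_real_,
                   verdict = "skipped_no_instruments",
                   stringsAsFactors = FALSE)
      })
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  structure(out, config = cfg, class = c("screen_table", "data.frame"))
}

#' Reverse MR screen (exclusion of reverse-causal pairs)
#'
#' For each forward-significant pair, fits the reverse-direction IVW
#' (outcome trait as exposure, original exposure as outcome) using the same
#' selection thresholds; pairs whose reverse IVW p falls below
#' `reverse_alpha` are re-labelled `excluded_reverse`. Forward-nonsignificant
#' rows are untouched; pairs with no reverse instruments keep their verdict
#' with `reverse_ivw_pval` absent.
#'
#' @param rows a `screen_table` from [run_forward_screen].
#' @param outcome_as_exposure the outcome trait's full [gwas_table].
#' @param targets named list of the original exposures' [gwas_table]s
#'   (names = exposure IDs), used as reverse-direction outcomes.
#' @param ld an `ld_info` or `NULL`.
#' @param cfg a [screen_config].
#' @return the updated `screen_table`.
#' @export
run_reverse_screen <- function(rows, outcome_as_exposure, targets, ld = NULL,
                               cfg = screen_config()) {
  iv <- select_instruments(outcome_as_exposure, ld, cfg$selection)
  for (i in seq_len(nrow(rows))) {
    if (!(rows$verdict[i] %in% c("significant_robust", "significant_unstable"))) next
    target <- targets[[rows$exposure_id[i]]]
    if (is.null(target) || nrow(iv) == 0) next
    h <- harmonize(iv, target)
    if (nrow(h) == 0) next
    fit <- mr_ivw(ratios_of(h))
    rows$reverse_ivw_pval[i] <- fit$pval
    if (fit$pval < cfg$reverse_alpha) rows$verdict[i] <- "excluded_reverse"
  }
  rows
}

#' @export
print.screen_table <- function(x, ...) {
  cat(sprintf("MR screen: %d exposures against '%s'\n", nrow(x),
              x$outcome_id[1]))
  print(table(verdict = x$verdict))
  invisible(x)
}

#' Assemble report tables from a screen
#'
#' Produces forest-plot-ready association tables, the mediation table and a
#' run manifest (thresholds, seed, counts) from screening output; written
#' as TSVs when `dir` is given.
#'
#' @param rows a `screen_table`.
#' @param mediation an `mr_mediation` table (may have 0 rows).
#' @param dir optional output directory for `associations.tsv`,
#'   `mediation.tsv` and `manifest.tsv`.
#' @return list with `associations`, `mediation`, `manifest`.
#' @export
build_report <- function(rows, mediation = NULL, dir = NULL) {
  assoc <- data.frame(exposure_id = rows$exposure_id,
                      outcome_id = rows$outcome_id,
                      nsnp = rows$nsnp,
                      or = rows$ivw_or,
                      ci_low = rows$ivw_ci_low, ci_high = rows$ivw_ci_high,
                      pval = rows$ivw_pval, verdict = rows$verdict,
                      stringsAsFactors = FALSE)
  med <- if (!is.null(mediation) && nrow(mediation) > 0) {
    data.frame(exposure = mediation$exposure_id,
               mediator = mediation$mediator_id,
               outcome = mediation$outcome_id,
               beta_all = mediation$beta_all,
               beta_indir = mediation$beta_indir,
               beta_dir = mediation$beta_dir,
               proportion = sprintf("%.2f%%", mediation$proportion_pct),
               flags = mediation$flags, stringsAsFactors = FALSE)
  } else {
    data.frame(exposure = character(), mediator = character(),
               outcome = character(), beta_all = numeric(),
               beta_indir = numeric(), beta_dir = numeric(),
               proportion = character(), flags = character(),
               stringsAsFactors = FALSE)
  }
  cfg <- attr(rows, "config") %||% screen_config()
  manifest <- data.frame(
    key = c("package_version", "seed", "p_threshold", "clump_r2",
            "clump_window_kb", "f_min", "ivw_alpha", "sensitivity_alpha",
            "reverse_alpha", "n_sim", "n_exposures", "n_significant_robust"),
    value = c(as.character(utils::packageVersion("mrmediate")),
              cfg$seed, cfg$selection$p_threshold, cfg$selection$clump_r2,
              cfg$selection$clump_window_kb, cfg$selection$f_min,
              cfg$ivw_alpha, cfg$sensitivity_alpha, cfg$reverse_alpha,
              cfg$n_sim, nrow(rows),
              sum(rows$verdict == "significant_robust")),
    stringsAsFactors = FALSE)
  out <- list(associations = assoc, mediation = med, manifest = manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.table(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}
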