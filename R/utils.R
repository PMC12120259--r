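# Internal helpers shared across the package.

# Two-sided 95% normal critical value, fixed so CI arithmetic is bit-stable
# across platforms and recorded in outputs.
Z95 <- 1.959964

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded internals (bootstrap SEs,
# MR-PRESSO simulations) do not perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Two-sided normal p-value from an estimate and its SE, clamped away from
# zero so extreme z-scores do not underflow below the representable range.
pval_normal <- function(beta, se) {
  pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
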