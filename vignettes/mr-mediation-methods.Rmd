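---
title: "Methods: two-sample MR screening and two-step mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening and two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The design

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics of two non-overlapping
cohorts, using genetic variants as instruments. A variant is a valid
instrument if it is (i) associated with the exposure, (ii) independent of
confounders, and (iii) affects the outcome only through the exposure.
`mrmediate` implements the full workflow used in microbiome/metabolite
screens against a disease endpoint: instrument selection, allele
harmonization, estimation, sensitivity analysis, bidirectional screening
across hundreds of exposures, and a two-step mediation decomposition
through an intermediate trait.

# Instrument selection

Four filters are applied in a fixed order; each removal is recorded in an
audit so that `kept + removed` always reconciles with the input.

1. **Association.** Keep variants with exposure p strictly below
   `p_threshold`. The default 1e-5 is the relaxed threshold commonly used
   when genome-wide significant instruments are too few (as is typical for
   microbial taxa with n of a few thousand); the boundary value is
   excluded (`p < threshold`).
2. **Confounders.** Remove SNPs on a user-supplied exclusion list (the
   static equivalent of a look-up in an association database for traits
   such as BMI or smoking).
3. **LD clumping.** Greedy index-SNP clumping: visit variants in ascending
   p (ties broken lexicographically by SNP ID, so the result is invariant
   to input row order); keep the visited variant and drop unprocessed
   variants on the same chromosome within `clump_window_kb` (default
   10,000 kb) whose r² with it is ≥ `clump_r2` (default 0.001). A pair
   missing from the LD table counts as r² = 0, matching sparse exports.
4. **Strength.** Per-SNP R² = 2·EAF·(1−EAF)·β² and
   F = R²(n−k−1)/(k(1−R²)) with k = 1; keep F strictly above `f_min`
   (default 10). The F formula contains k because it also serves the
   overall-instrument report (`overall_f`, k = number of instruments kept),
   but the filter is per-SNP, which matches how the statistic is used in
   summary-data screens. Records lacking EAF cannot be scored and fail
   this stage explicitly rather than silently passing.

# Harmonization

Variants are matched by SNP ID alone (rsIDs are the stable key in public
summary statistics; chromosome/position are carried but not used for
joining). Outcome effects are aligned to the exposure's effect allele:
identical coding is kept, swapped coding negates the outcome beta and
reflects its EAF, and strand flips are reconciled through the complement
before declaring a variant incompatible. Palindromic variants (A/T, C/G)
are eliminated unconditionally by default, since their strand cannot be
resolved from alleles; an optional frequency rescue keeps a palindrome when
both studies' EAFs lie outside [0.42, 0.58] and agree on the minor allele.
The default follows the stricter practice; the rescue exists for
sensitivity runs.

# Estimators

With Wald ratios θ_j = β_out,j / β_exp,j, first-order standard errors
se_j = se_out,j / |β_exp,j| and weights w_j = se_j⁻²:

* **IVW** — β = Σw_jθ_j / Σw_j. The default standard error is
  multiplicative random-effects: the fixed-effect SE (Σw)^(−1/2) inflated
  by max(1, √(Q/(n−1))). It reduces to the fixed-effect model under
  homogeneity and never reports less uncertainty than it; this is the
  dominant convention in two-sample MR software. P-values are two-sided
  normal.
* **MR-Egger** — weighted least squares of outcome on exposure effects
  with an intercept, weights 1/se_out², after orienting each variant so
  its exposure effect is non-negative (the estimator is defined on that
  orientation). Coefficient SEs use the residual SD floored at 1;
  p-values use t with n−2 df. The intercept estimates the average
  directional pleiotropy; the slope is the adjusted causal effect.
* **Weighted median** — the 0.5-quantile of the ratio distribution under
  standardized cumulative weights s_j = (Σ_{i≤j}w_i − w_j/2)/Σw, linearly
  interpolated. Consistent while valid instruments carry > 50% of the
  weight. Its SE is a seeded parametric bootstrap (default 1000
  replicates), so results are reproducible; the bootstrap draws each ratio
  from Normal(θ_j, se_j).

Odds ratios use exp(β) with a 95% CI exp(β ± z·se) at the fixed critical
value z = 1.959964 (recorded in the fitted object), so the geometric mean
of the CI bounds equals the OR exactly — a property used as a consistency
check on published tables.

# Sensitivity suite

* **Cochran's Q** uses the fixed-effect IVW center (the standard
  definition) even when the headline IVW is random-effects, with a
  chi-square(n−1) p-value.
* **Leave-one-out** recomputes the IVW without each SNP; a row is flagged
  when dropping that SNP flips the sign or moves the estimate across the
  significance boundary.
* **MR-PRESSO** computes the observed weighted residual sum of squares
  around leave-one-out IVW slopes and simulates its null distribution
  (default 1000 seeded replicates) by redrawing both exposure and outcome
  effects from their sampling distributions. The global p-value uses the
  add-one estimator (1 + #{RSS* ≥ RSS})/(n_sim + 1), so it can never be
  zero and its smallest attainable value is 1/(n_sim+1), reached when the
  observed RSS exceeds every simulated one. Per-SNP outlier p-values
  compare each observed residual with its own simulated distribution,
  Bonferroni-corrected over the number of instruments at level 0.05. When
  outliers are removed, the corrected IVW and a distortion test (observed
  relative change versus its simulated null distribution) are reported;
  both are absent when nothing is removed.

# Screening verdicts

A pair is `significant_robust` when IVW p < 0.05, the MR-Egger slope
shares IVW's sign (weighted-median concordance is optional and off by
default), and none of Q, the Egger intercept or the PRESSO global test is
significant at the sensitivity level (default 0.05). Violating
concordance or a sensitivity alarm demotes to `significant_unstable`;
pairs with reverse-direction IVW p < 0.05 become `excluded_reverse`.
Nominal p < 0.05 with no multiplicity correction mirrors the screening
practice this pipeline reproduces; verdicts are recomputable from the
stored statistics, and the run manifest records every threshold and seed.
Note that sensitivity alarms fire at their nominal 5% rate even for true
effects, so across a battery a minority of genuinely causal exposures
will be labelled `significant_unstable`.

# Two-step mediation

The total effect β_all (exposure→outcome), β1 (exposure→mediator) and β2
(mediator→outcome) are each IVW estimates. The decomposition is

β_indir = β1·β2, β_dir = β_all − β_indir, proportion = β_indir/β_all,

with a delta-method SE for the product, √(β1²se2² + β2²se1²), and a 95%
CI as an extension (published tables of this design print no mediation
CIs). Proportions are formatted as percentages rounded half-up to two
decimals. Rows with sign(β_indir) ≠ sign(β_all) or proportion outside
[0, 1] are emitted with flags rather than suppressed.

For β2, instruments are selected from the mediator's GWAS *excluding SNPs
that reach the instrument threshold for the exposure* (via the
confounder-exclusion mechanism). Using the exposure's instruments for the
mediator step would let the direct path contaminate β2 (bias of order
β_dir/β1); mediator-specific instruments keep the second step clean. The
gate for emitting a decomposition is nominal significance of all three
links.

# The synthetic-data generator

`simulate_triplet()` draws summary statistics directly from their
asymptotic sampling distributions — no individual-level genotypes — which
is sufficient for two-sample MR (only summary data enter the estimators)
and orders of magnitude faster. For SNP j: maf ~ Uniform(maf_range),
instrument effect γ_j ~ N(0, gamma_sd²), per-trait SE
1/√(n·2·maf(1−maf)) (standardized-trait approximation, also used for
log-odds effects of the binary outcome at this scale), observed effects
drawn around the true ones. True mediator effects are β1γ_j (plus the
effects of mediator-specific instrument SNPs, which have no exposure
effect), and true outcome effects β_dir·γ_j + β2·δ_j plus pleiotropy.

Choices that matter:

* **Sample sizes** default to the scale of the public GWAS this design
  targets (exposure 5,959; mediator 8,299; outcome 368,519) and
  `gamma_sd = 0.15` so a p < 1e-5 screen yields tens of instruments with
  F comfortably above 10 at those sizes — the regime the pipeline is
  meant for.
* **Directional pleiotropy** α_j ~ N(pleiotropy_mean, pleiotropy_sd²) is
  applied on the exposure-increasing allele. Because allele coding is
  arbitrary, pleiotropy defined per coded allele would be symmetrized by
  MR-Egger's orientation step and could never be "directional"; aligning
  it with the exposure-increasing allele is the standard construction and
  keeps the magnitude independent of instrument strength (the InSIDE
  condition).
* **Outliers** shift the outcome effect by `outlier_shift` outcome SEs.
  In the outlier scenario all three sample sizes are 50,000 so that a
  10-SE displacement is a genuine ~10-SD anomaly of the PRESSO residual;
  with a very large outcome GWAS the residual scale is dominated by
  exposure noise and the same displacement shrinks to ~2 SD, which is a
  statement about the scenario, not about the test.
* The three cohorts are independent (the two-sample assumption); sample
  overlap, real LD panels and ascertainment are not modeled. Generated
  tables always pass the I/O validators, and identical seeds give
  bit-identical output.

What passing the simulation suite does **not** show: performance under
sample overlap, under correlated pleiotropy (InSIDE violations), with
misreported allele frequencies, or at biobank-scale polygenicity. The
generator is a calibration harness, not a population-genetics model.

## Scenario presets and calibration surface

* `null` (30 SNPs, no effects): across 2,000 replicates the IVW screen
  rejects at 3–7% at α = 0.05 (slightly conservative because the
  random-effects SE never deflates).
* `mediation` (β1 = 0.4, β2 = 0.3, β_dir = 0.1, 80 + 80 SNPs,
  n = 50,000): across 500 replicates the mean estimated proportion
  mediated sits within two Monte-Carlo SEs of the true
  0.12/0.22 ≈ 54.5%, and the IVW 95% CI covers the true total effect in
  95% ± 3% of runs.
* `pleiotropy` (every SNP invalid, mean 0.05): the Egger intercept is an
  unbiased estimate of the injected mean (its single-dataset z-statistic
  is calibrated, so any one seed lands outside ±2 about 5–10% of the
  time; the replicated mean is what the acceptance script reports).
* `invalid40` (40% invalid, directional mean 0.1): the weighted median's
  error stays within twice its own sampling SD across replicates while
  IVW's does not. A note on the yardstick: with ~40% of weight displaced
  one-sidedly, the weighted median retains a finite-sample bias of the
  order of the per-ratio noise (the 0.5-quantile sits near the 83rd
  percentile of the valid ratios). That bias does not vanish relative to
  the bootstrap SE as instruments accumulate, so the meaningful
  robustness statement — made here and in the acceptance checks — is
  about the estimator's sampling distribution over replicates and about
  its error relative to IVW's, not about any single dataset's bootstrap
  interval.
* `outlier` (one 10-SD outlier among 30 SNPs): MR-PRESSO flags the
  injected SNP in ≥ 95 of 100 replicates with 1,000 null simulations
  (with 500 simulations the Bonferroni-corrected floor 30/501 ≈ 0.06
  cannot clear α = 0.05 at 30 instruments — the simulation count bounds
  the detectable outlier p-value).

Problem sizes above (2,000 / 500 / 100 replicates) are the package's
standing calibration sizes; they keep Monte-Carlo error well below each
property's tolerance.

# Numerical conventions and degenerate inputs

* z = 1.959964 fixed for all 95% intervals; p-values clamped at the
  smallest positive normal double so extreme associations never underflow
  to an invalid 0.
* Boundary semantics: `p < threshold` (strict), `F > f_min` (strict),
  `r² ≥ clump_r2` prunes.
* A Wald ratio with β_exp = 0 is a degenerate-instrument error; an empty
  instrument set is not an error in the screen (the pair is skipped with
  a recorded verdict) but is one in the estimators.
* The weighted median returns the extreme order statistic when s = 0.5
  falls outside the interpolation range (possible with one dominating
  weight).
* MR-PRESSO requires ≥ 4 instruments, Egger ≥ 3, the median ≥ 2; the
  add-one p-value estimator keeps all simulated p-values in
  [1/(n_sim+1), 1].
* Full-precision serialization (17 significant digits) makes table
  round-trips exact, including signed zero, which re-reads as 0.

# Known limitations

* Matching by rsID only: multi-allelic sites and ID-less variants are out
  of scope, as is liftover or reference-genome harmonization.
* The subtraction decomposition assumes the linear structural model;
  no multivariable-MR direct-effect estimation is provided.
* Confounder screening is a static list, not a live association lookup.
* The reverse screen, like the design it reproduces, can mislabel a
  forward-causal pair as reverse-causal when the outcome GWAS is so much
  larger that the exposure's instruments dominate the outcome's
  instrument set; in practice the outcome's own instruments dilute this,
  and the screening tests construct their fixtures accordingly.
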