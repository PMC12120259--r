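Package: mrmediate
Title: Two-Sample Bidirectional Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection (p-value threshold, LD clumping,
    per-SNP F-statistic, confounder exclusion), allele harmonization with
    palindromic-variant removal, causal estimation by inverse-variance
    weighting, MR-Egger regression and the weighted median, a sensitivity
    suite (Cochran's Q, Egger intercept, leave-one-out, MR-PRESSO), a
    bidirectional screening pipeline across many exposures, and two-step
    mediation decomposition of a total effect into indirect and direct
    components with the proportion mediated. Includes a summary-level GWAS
    simulator with known causal structure for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
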