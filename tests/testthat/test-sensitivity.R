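test_that("Cochran's Q matches hand arithmetic and its chi-square oracle", {
  # identical ratios: Q = 0, p = 1
  r0 <- wald_ratio(rep(1, 3), rep(0.1, 3), rep(0.2, 3), c(0.1, 0.2, 0.05))
  q0 <- cochran_q(r0)
  expect_equal(q0$q_stat, 0)
  expect_equal(q0$q_pval, 1)
  # two-SNP fixture: Q = 100 (0.2 - 0.28)^2 + 400 (0.3 - 0.28)^2 = 0.8
  r <- wald_ratio(c(1, 1), c(0.1, 0.1), c(0.2, 0.3), c(0.1, 0.05))
  q <- cochran_q(r)
  expect_equal(q$q_stat, 0.8, tolerance = 1e-12)
  expect_equal(q$q_df, 1L)
  expect_equal(q$q_pval, pchisq(0.8, 1, lower.tail = FALSE))
  expect_equal(q$q_pval, 0.371, tolerance = 1e-3)
  # duplicating every SNP exactly doubles Q (same center, twice the terms)
  rdup <- rbind(r, r)
  expect_equal(cochran_q(rdup)$q_stat, 2 * q$q_stat, tolerance = 1e-12)
  expect_error(cochran_q(r[1, , drop = FALSE]), "at least 2")
})

test_that("Q relates to the equal-weight heterogeneity identity", {
  # with equal weights w, Q = w * (n-1) * var_pop(theta)
  th <- c(0.1, 0.4, -0.2, 0.3, 0.05)
  r <- wald_ratio(rep(1, 5), rep(0.01, 5), th, rep(0.1, 5))
  q <- cochran_q(r)
  expect_equal(q$q_stat, 100 * sum((th - mean(th))^2), tolerance = 1e-10)
})

test_that("leave-one-out equals direct recomputation and flags outliers", {
  # all ratios equal: every left-out estimate is the same constant
  h0 <- harmonized_pairs(rep(1, 4), rep(0.1, 4), rep(0.3, 4), rep(0.1, 4))
  loo0 <- leave_one_out(h0)
  expect_equal(loo0$beta, rep(0.3, 4))
  expect_equal(nrow(loo0), 4)
  expect_false(any(loo0$flag))

  # one gross outlier among 10 concordant SNPs
  set.seed(11)
  bx <- rnorm(10, 0.3, 0.02)
  by <- 0.2 * bx + rnorm(10, 0, 0.005)
  by[4] <- by[4] + 0.5
  h <- harmonized_pairs(bx, rep(0.02, 10), by, rep(0.02, 10))
  loo <- leave_one_out(h)
  full <- attr(loo, "full")
  # oracle: recompute the 10 reduced IVWs directly
  for (j in 1:10) {
    direct <- mr_ivw(wald_ratio(bx[-j], 0.02, by[-j], 0.02))
    expect_equal(loo$beta[j], direct$beta, tolerance = 1e-12)
    expect_equal(loo$se[j], direct$se, tolerance = 1e-12)
  }
  departures <- abs(loo$beta - full$beta)
  expect_equal(which.max(departures), 4L)

  # nsnp = 2: each row is the other SNP's Wald ratio
  h2 <- harmonized_pairs(c(0.2, 0.4), c(0.02, 0.02), c(0.05, 0.02),
                         c(0.01, 0.01))
  loo2 <- leave_one_out(h2)
  expect_equal(loo2$beta, c(0.02 / 0.4, 0.05 / 0.2))
  expect_error(leave_one_out(h2[1, , drop = FALSE]), "at least 2")
})

test_that("loo flags are a deterministic function of the table", {
  h <- harmonized_pairs(rep(1, 5), rep(0.1, 5), c(0.3, 0.31, 0.29, 0.3, 0.32),
                        rep(0.05, 5))
  l1 <- leave_one_out(h)
  l2 <- leave_one_out(h)
  expect_identical(l1, l2)
})

presso_fixture <- function(seed = 13, n = 30, outlier = FALSE) {
  cfg <- if (outlier) sim_scenario("outlier", seed = seed, n_snps = n)
  else sim_scenario("null", seed = seed, n_snps = n, beta_dir = 0.2)
  sim <- simulate_triplet(cfg)
  iv <- select_instruments(sim$exposure)
  list(h = harmonize(iv, sim$outcome), truth = sim$truth)
}

test_that("MR-PRESSO global test is calm under no pleiotropy", {
  sim <- simulate_triplet(sim_scenario("null", seed = 11, n_snps = 30,
                                       n_med_snps = 0))
  iv <- select_instruments(sim$exposure)
  h <- harmonize(iv, sim$outcome)
  p <- mr_presso(h, n_sim = 500, seed = 11)
  expect_gt(p$global_pval, 0.05)
  expect_length(p$outlier_snps, 0)
  expect_null(p$beta_corrected)
  expect_gte(p$global_pval, 1 / 501)
})

test_that("MR-PRESSO flags an injected 10-SD outlier and corrects the IVW", {
  set.seed(13)
  n <- 15
  bx <- runif(n, 0.1, 0.3)
  sy <- rep(0.02, n)
  by <- 0.2 * bx + rnorm(n, 0, sy)
  by[7] <- 0.2 * bx[7] + 10 * sy[7]   # single 10-SD displacement
  h <- harmonized_pairs(bx, rep(0.01, n), by, sy)
  p <- mr_presso(h, n_sim = 500, seed = 13)
  expect_true("rs7" %in% p$outlier_snps)
  expect_lt(p$global_pval, 0.05)
  # corrected IVW equals IVW on the clean subset
  keep <- !(h$snp_id %in% p$outlier_snps)
  direct <- mr_ivw(wald_ratio(h$beta_exp[keep], h$se_exp[keep],
                              h$beta_out[keep], h$se_out[keep]),
                   mode = "fixed")
  expect_equal(p$beta_corrected, direct$beta, tolerance = 1e-12)
  expect_true(!is.null(p$distortion_pval))
  # the corrected estimate moves toward the truth
  full <- mr_ivw(ratios_full <- wald_ratio(bx, 0.01, by, sy), mode = "fixed")
  expect_lt(abs(p$beta_corrected - 0.2), abs(full$beta - 0.2))
})

test_that("MR-PRESSO is deterministic and invariant to SNP order", {
  fx <- presso_fixture(seed = 17)
  p1 <- mr_presso(fx$h, n_sim = 300, seed = 5)
  p2 <- mr_presso(fx$h, n_sim = 300, seed = 5)
  expect_identical(p1$global_pval, p2$global_pval)
  expect_identical(p1$rss_obs, p2$rss_obs)
  # reordering the SNPs does not change the observed RSS
  perm <- fx$h[rev(seq_len(nrow(fx$h))), ]
  p3 <- mr_presso(perm, n_sim = 300, seed = 5)
  expect_equal(p3$rss_obs, p1$rss_obs, tolerance = 1e-10)
  expect_error(mr_presso(fx$h[1:3, ]), "at least 4")
  expect_warning(mr_presso(fx$h, n_sim = 50, seed = 1), "n_sim")
})

test_that("the global p-value hits the add-one floor for extreme RSS", {
  # one variant displaced far beyond anything the null can simulate:
  # the observed RSS exceeds every simulated RSS, p = 1/(n_sim+1)
  bx <- c(0.2, 0.25, 0.3, 0.35, 0.4, 0.45)
  by <- 0.3 * bx
  by[3] <- by[3] + 2  # ~100 outcome SEs
  h <- harmonized_pairs(bx, rep(0.01, 6), by, rep(0.02, 6))
  p <- mr_presso(h, n_sim = 200, seed = 3)
  expect_equal(p$global_pval, 1 / 201)
  # and a perfectly fitting set sits at the opposite boundary, p = 1
  h0 <- harmonized_pairs(bx, rep(0.05, 6), 0.3 * bx, rep(0.05, 6))
  expect_equal(mr_presso(h0, n_sim = 200, seed = 3)$global_pval, 1)
})

test_that("PRESSO type-I error is near nominal under the null", {
  # reduced replication of the null scenario
  n_rep <- 200
  rejections <- 0
  for (i in seq_len(n_rep)) {
    sim <- simulate_triplet(sim_config(n_snps = 10, n_med_snps = 0,
                                       n_exp = 20000, n_out = 20000,
                                       gamma_sd = 0.15, seed = 20000 + i))
    h <- harmonize(sim$exposure, sim$outcome)
    p <- mr_presso(h, n_sim = 150, seed = i)
    if (p$global_pval < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / n_rep, 0.01)
  expect_lte(rejections / n_rep, 0.09)
})

test_that("sensitivity_report bundles Q, Egger intercept, loo and PRESSO", {
  fx <- presso_fixture(seed = 19)
  s <- sensitivity_report(fx$h, n_sim = 200, seed = 7)
  expect_equal(s$q_df, nrow(fx$h) - 1L)
  expect_equal(nrow(s$loo), nrow(fx$h))
  expect_false(is.na(s$egger_intercept))
  expect_s3_class(s$presso, "mr_presso")
  # n_sim = 0 skips PRESSO
  expect_null(sensitivity_report(fx$h, n_sim = 0)$presso)
})
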