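test_that("wald_ratio does the per-SNP division and weighting", {
  r <- wald_ratio(0.2, 0.05, 0.06, 0.02)
  expect_equal(r$wald, 0.3)
  r2 <- wald_ratio(0.1, 0.03, 0.02, 0.01)
  expect_equal(r2$wald, 0.2)
  expect_equal(r2$wald_se, 0.1)
  expect_equal(r2$weight, 100)
  r3 <- wald_ratio(-0.2, 0.05, 0, 0.02)
  expect_equal(r3$wald, 0)
  expect_equal(r3$wald_se, 0.02 / 0.2)
  expect_error(wald_ratio(0, 0.05, 0.1, 0.02), "degenerate")
})

test_that("IVW is the precision-weighted mean of ratios", {
  r <- wald_ratio(c(1, 1), c(0.1, 0.1), c(0.2, 0.3), c(0.1, 0.05))
  fit <- mr_ivw(r)
  expect_equal(fit$beta, (100 * 0.2 + 400 * 0.3) / 500)  # = 0.28
  # homogeneous ratios: Q = 0, mode-independent se = (sum w)^(-1/2)
  rh <- wald_ratio(c(1, 1, 1), c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2),
                   c(0.1, 0.2, 0.05))
  expect_equal(mr_ivw(rh, "fixed")$beta, 0.2)
  expect_equal(mr_ivw(rh, "multiplicative_random")$se,
               mr_ivw(rh, "fixed")$se)
  expect_equal(mr_ivw(rh, "fixed")$se, sum(rh$weight)^-0.5)
  # single SNP: IVW reduces to the Wald ratio
  r1 <- wald_ratio(0.1, 0.02, 0.03, 0.01)
  f1 <- mr_ivw(r1)
  expect_equal(f1$beta, r1$wald)
  expect_equal(f1$se, r1$wald_se)
  expect_equal(f1$nsnp, 1L)
  # equal weights: IVW equals the arithmetic mean
  re <- wald_ratio(rep(1, 4), rep(0.1, 4), c(0.1, 0.2, 0.3, 0.4), rep(0.1, 4))
  expect_equal(mr_ivw(re, "fixed")$beta, 0.25)
  expect_error(mr_ivw(re[0, ]), "empty")
})

test_that("random-effects IVW inflates the SE under heterogeneity only", {
  r <- wald_ratio(rep(1, 4), rep(0.01, 4), c(0.1, 0.5, -0.2, 0.9), rep(0.05, 4))
  q <- cochran_q(r)
  expect_gt(q$q_stat, 3)  # heterogeneous by construction
  expect_equal(mr_ivw(r, "multiplicative_random")$se,
               mr_ivw(r, "fixed")$se * sqrt(q$q_stat / 3))
})

test_that("MR-Egger recovers an exact line and its intercept", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- harmonized_pairs(beta_exp = bx, se_exp = rep(0.01, 4),
                        beta_out = 0.05 + 0.4 * bx, se_out = rep(0.02, 4))
  e <- mr_egger(h)
  expect_equal(e$intercept, 0.05, tolerance = 1e-10)
  expect_equal(e$slope$beta, 0.4, tolerance = 1e-10)
  # through the origin: intercept 0
  h0 <- harmonized_pairs(beta_exp = bx, se_exp = rep(0.01, 4),
                         beta_out = 0.25 * bx, se_out = rep(0.02, 4))
  expect_equal(mr_egger(h0)$intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(h0[1:2, ]), "at least 3")
})

test_that("MR-Egger orients exposure effects to be non-negative", {
  bx <- c(0.1, -0.2, 0.3, -0.4)
  # on the oriented scale (|bx|) the points lie on 0.05 + 0.4 x
  h <- harmonized_pairs(beta_exp = bx, se_exp = rep(0.01, 4),
                        beta_out = sign(bx) * (0.05 + 0.4 * abs(bx)),
                        se_out = rep(0.02, 4))
  e <- mr_egger(h)
  expect_equal(e$intercept, 0.05, tolerance = 1e-10)
  expect_equal(e$slope$beta, 0.4, tolerance = 1e-10)
})

test_that("weighted median interpolates the weighted ratio distribution", {
  # equal weights, 3 ratios: s = 0.5 falls on the middle order statistic
  r <- wald_ratio(rep(1, 3), rep(0.1, 3), c(0.1, 0.2, 0.9), rep(0.1, 3))
  expect_equal(mr_weighted_median(r, n_boot = 50, seed = 1)$beta, 0.2)
  # two equal-weight ratios: midpoint by interpolation
  r2 <- wald_ratio(rep(1, 2), rep(0.1, 2), c(0.1, 0.3), rep(0.1, 2))
  expect_equal(mr_weighted_median(r2, n_boot = 50, seed = 1)$beta, 0.2)
  # degenerate distribution: estimate = c, bootstrap SE small as SEs shrink
  r3 <- wald_ratio(rep(1, 5), rep(0.1, 5), rep(0.37, 5), rep(1e-5, 5))
  fit3 <- mr_weighted_median(r3, n_boot = 200, seed = 2)
  expect_equal(fit3$beta, 0.37)
  expect_lt(fit3$se, 1e-4)
  expect_error(mr_weighted_median(r3[1, , drop = FALSE]), "at least 2")
  # estimate always lies within the ratio range
  set.seed(3)
  for (i in 1:20) {
    th <- rnorm(7); se <- runif(7, 0.05, 0.3)
    ri <- wald_ratio(rep(1, 7), rep(0.01, 7), th, se)
    est <- mr_weighted_median(ri, n_boot = 10, seed = i)$beta
    expect_gte(est, min(th)); expect_lte(est, max(th))
  }
})

test_that("weighted median resists <50% contamination better than IVW", {
  # 60% of weight at the truth 0.2, 40% shifted by +1
  th <- c(rep(0.2, 6), rep(1.2, 4))
  ri <- wald_ratio(rep(1, 10), rep(0.01, 10), th, rep(0.1, 10))
  wm <- mr_weighted_median(ri, n_boot = 100, seed = 4)$beta
  ivw <- mr_ivw(ri)$beta
  expect_lt(abs(wm - 0.2), abs(ivw - 0.2))
})

test_that("odds-ratio conversion is log-symmetric at z = 1.959964", {
  null <- to_odds_ratio(0, 0.1)
  expect_equal(null$or, 1)
  expect_equal(null$ci_low * null$ci_high, 1, tolerance = 1e-12)
  # published-style rounding: beta 0.2070, se 0.0806 -> 1.23 (1.05-1.44)
  x <- to_odds_ratio(0.2070, 0.0806)
  expect_equal(round(x$or, 2), 1.23)
  expect_equal(round(x$ci_low, 2), 1.05)
  expect_equal(round(x$ci_high, 2), 1.44)
  # inversion arithmetic: recover a protective CI from its log-scale parts
  y <- to_odds_ratio(log(0.65), (log(0.86) - log(0.49)) / (2 * 1.959964))
  expect_equal(round(y$ci_low, 2), 0.49)
  expect_equal(round(y$ci_high, 2), 0.86)
  # geometric mean of the CI equals the OR for arbitrary inputs
  set.seed(5)
  b <- rnorm(20); s <- runif(20, 0.01, 1)
  z <- to_odds_ratio(b, s)
  expect_equal(sqrt(z$ci_low * z$ci_high), z$or, tolerance = 1e-12)
})

test_that("estimators are sign- and scale-equivariant", {
  set.seed(6)
  bx <- rnorm(8, 0.2, 0.05); sx <- runif(8, 0.01, 0.03)
  by <- 0.3 * bx + rnorm(8, 0, 0.02); sy <- runif(8, 0.01, 0.03)
  h <- harmonized_pairs(bx, sx, by, sy)
  hneg <- harmonized_pairs(bx, sx, -by, sy)
  fit <- mr_fit(h, seed = 9)
  fitneg <- mr_fit(hneg, seed = 9)
  expect_equal(fitneg$results$beta, -fit$results$beta)
  # IVW and Egger SEs are exactly sign-invariant; the weighted median's
  # bootstrap SE only stochastically so
  exact <- fit$results$method != "weighted_median"
  expect_equal(fitneg$results$se[exact], fit$results$se[exact])
  expect_equal(fitneg$results$se[!exact], fit$results$se[!exact],
               tolerance = 0.2)
  # scaling exposure units by c divides ratio estimates by c
  c0 <- 2.5
  hsc <- harmonized_pairs(c0 * bx, c0 * sx, by, sy)
  expect_equal(mr_ivw(wald_ratio(hsc$beta_exp, hsc$se_exp, hsc$beta_out,
                                 hsc$se_out))$beta,
               mr_ivw(wald_ratio(bx, sx, by, sy))$beta / c0)
})

test_that("mr_fit bundles estimators with a stable interface", {
  set.seed(8)
  bx <- rnorm(10, 0.2, 0.05)
  h <- harmonized_pairs(bx, rep(0.02, 10), 0.25 * bx + rnorm(10, 0, 0.01),
                        rep(0.01, 10))
  fit <- mr_fit(h, seed = 3)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$results$method, c("ivw", "egger", "weighted_median"))
  expect_named(coef(fit), fit$results$method)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < ci[, 2]))
  expect_equal(fit$results$or, exp(fit$results$beta))
  # same seed, same weighted-median SE; output is reproducible
  expect_equal(mr_fit(h, seed = 3)$results, fit$results)
  expect_output(print(fit), "ivw")
  expect_error(mr_fit(h[0, ]), "empty")
})
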