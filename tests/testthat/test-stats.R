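test_that("hedges_g reproduces worked examples and is antisymmetric", {
  expect_equal(round(hedges_g(0.06, 0.05, -0.03, 0.04, 14, 14), 3), -1.988)
  expect_equal(round(hedges_g(13.79, 6.37, 71.64, 20.59, 14, 14), 3), 3.796)
  expect_equal(hedges_g(5, 2, 5, 3, 10, 10), 0)
  expect_equal(hedges_g(1, 2, 4, 3, 12, 12),
               -hedges_g(4, 3, 1, 2, 12, 12))
  # unequal n uses the general pooled SD
  expect_equal(hedges_g(0, 1, 1, 1, 10, 20), 1)
  # small-sample correction shrinks towards zero
  g <- hedges_g(0, 1, 1, 1, 14, 14)
  gj <- hedges_g(0, 1, 1, 1, 14, 14, small_sample_correction = TRUE)
  expect_equal(gj, g * (1 - 3 / (4 * 28 - 9)))
  expect_error(hedges_g(1, 0, 2, 0, 10, 10), "zero")
  expect_error(hedges_g(1, 1, 2, 1, 1, 10), "at least 2")
})

test_that("the g confidence interval matches its printed examples", {
  g <- hedges_g(13.79, 6.37, 71.64, 20.59, 14, 14)
  ci <- g_confidence_interval(g, 14, 14)
  expect_equal(round(ci$lower, 3), 2.556)
  expect_equal(round(ci$upper, 3), 5.036)
  null <- g_confidence_interval(0, 14, 14)
  expect_equal(null$lower, -0.741, tolerance = 1e-3)
  expect_equal(null$upper, 0.741, tolerance = 1e-3)
  # symmetry about g, width grows with |g| and shrinks with n
  any_ci <- g_confidence_interval(1.3, 14, 14)
  expect_equal((any_ci$lower + any_ci$upper) / 2, 1.3)
  expect_gt(g_confidence_interval(2, 14, 14)$se,
            g_confidence_interval(1, 14, 14)$se)
  expect_lt(g_confidence_interval(1, 50, 50)$se,
            g_confidence_interval(1, 14, 14)$se)
  expect_error(g_confidence_interval(1, 14, 14, level = 1.2), "between")
})

test_that("the paired test gates on normality and matches hand arithmetic", {
  res <- paired_test(c(1, 2, 3), c(2, 4, 3))
  expect_equal(res$method, "paired t")
  expect_equal(res$statistic, 1.732, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(res$mean_diff, 1)
  expect_error(paired_test(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(paired_test(1:2, 2:3), "at least 3")
  # heavy-tailed differences fall back to the signed-rank test
  set.seed(1)
  x <- rep(0, 20)
  y <- c(rcauchy(19), 40)
  res2 <- paired_test(x, y)
  if (!res2$normal) expect_equal(res2$method, "wilcoxon")
})

test_that("rejection rate of the paired test matches noncentral-t power", {
  n <- 14
  dz <- 0.6
  tc <- qt(0.975, n - 1)
  ncp <- dz * sqrt(n)
  theory <- 1 - pt(tc, n - 1, ncp) + pt(-tc, n - 1, ncp)
  set.seed(99)
  hits <- replicate(2000, {
    x <- rnorm(n)
    y <- x + rnorm(n, mean = dz, sd = 1)
    # sd of the paired differences is 1, so dz is the true effect size
    paired_test(x, y)$p_value < 0.05
  })
  expect_equal(mean(hits), theory, tolerance = 0.04)
})

test_that("Bonferroni levels reproduce the two study families", {
  a16 <- bonferroni_alpha(0.05, 16)
  expect_equal(a16$alpha, 0.05 / 16)
  expect_equal(a16$alpha_4dp, 0.0031)
  expect_equal(bonferroni_alpha(0.05, 2)$alpha, 0.025)
  expect_equal(bonferroni_alpha(0.05, 1)$alpha, 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "at least 1")
})

test_that("partial correlation equals explicit two-stage residualization", {
  set.seed(3)
  n <- 40
  z <- cbind(a = rnorm(n), b = rnorm(n))
  x <- 0.5 * z[, 1] + rnorm(n)
  y <- -0.3 * z[, 2] + 0.4 * x + rnorm(n)
  pc <- partial_correlation(x, y, z)
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  expect_equal(pc$r_partial, cor(rx, ry), tolerance = 1e-10)
  expect_equal(pc$df, n - 4)
  # constant covariates reduce to the plain Pearson correlation
  pc0 <- partial_correlation(x, y, cbind(c1 = rep(1, n), c2 = rep(2, n)))
  expect_equal(pc0$r_partial, cor(x, y), tolerance = 1e-10)
  # perfectly related residuals
  pc1 <- partial_correlation(x, 2 * x + z[, 1], cbind(z[, 1]))
  expect_equal(pc1$r_partial, 1, tolerance = 1e-10)
  expect_error(partial_correlation(x, y, cbind(z[, 1], 2 * z[, 1])),
               "collinear")
  expect_error(partial_correlation(1:4, 1:4, z[1:4, ]), "observations")
})

test_that("6-point hand-checkable partial correlation matches the oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  z <- cbind(c(1, 1, 2, 2, 3, 3))
  pc <- partial_correlation(x, y, z)
  expect_equal(pc$r_partial, cor(resid(lm(x ~ z)), resid(lm(y ~ z))),
               tolerance = 1e-10)
})

test_that("the sensitivity computation solves the noncentral-t power
           equation", {
  dz <- sensitivity_dz(14)
  # the root actually achieves the requested power
  tc <- qt(0.975, 13)
  pw <- 1 - pt(tc, 13, ncp = dz * sqrt(14)) + pt(-tc, 13, ncp = dz * sqrt(14))
  expect_equal(pw, 0.80, tolerance = 1e-8)
  expect_equal(dz, 0.81, tolerance = 0.01)
  # large-n limit: (z_{1-a/2} + z_power) / sqrt(n)
  n <- 5000
  expect_equal(sensitivity_dz(n),
               (qnorm(0.975) + qnorm(0.8)) / sqrt(n), tolerance = 1e-3)
  # at 50 % power the detectable effect sits near t_crit / sqrt(n)
  # the median of a noncentral t sits slightly below its noncentrality
  expect_equal(sensitivity_dz(14, power = 0.5), qt(0.975, 13) / sqrt(14),
               tolerance = 0.025)
  expect_error(sensitivity_dz(14, power = 1.5), "power")
})
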