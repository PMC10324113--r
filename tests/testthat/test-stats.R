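# Downstream statistics: percent change, variance-equality tests, eta
# ANOVA, correlations, ddCt, group summaries.

test_that("percent change reproduces the reported group contrasts", {
  expect_equal(round(percent_change(195.4, 131.1), 1), -32.9)
  expect_equal(round(percent_change(195.4, 131.1)), -33)
  expect_equal(round(percent_change(353.8, 617.5), 1), 74.5)
  expect_equal(round(percent_change(353.8, 617.5)), 75)
  expect_identical(percent_change(42, 42), 0)
  expect_error(percent_change(0, 10), "ref_mean")
})

test_that("variance-ratio F test: examples, antisymmetry, degeneracies", {
  x <- c(1, 2, 3, 4, 5)
  same <- variance_ratio_test(x, x)
  expect_equal(same$statistic, 1)
  expect_equal(same$p, 1)
  r <- variance_ratio_test(x, 2 * x)
  expect_equal(r$statistic, 0.25)
  expect_equal(r$p, 2 * pf(0.25, 4, 4), tolerance = 1e-12)
  expect_equal(r$p, 0.208, tolerance = 1e-2)
  # swapping samples inverts F and keeps p
  r2 <- variance_ratio_test(2 * x, x)
  expect_equal(r2$statistic, 4)
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  y <- c(1, 2, 4, 9)
  expect_warning(r3 <- variance_ratio_test(y, c(5, 5, 5)), "zero variance")
  expect_identical(r3$p, 0)
  expect_error(variance_ratio_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(variance_ratio_test(1, c(1, 2)), "n >= 2")
})

test_that("one-way ANOVA equals the squared pooled t for two groups", {
  set.seed(31)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(11, mean = 0.4)
    r <- anova_oneway(c(a, b), rep(c("a", "b"), c(8, 11)))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  }
  expect_error(anova_oneway(1:5, rep("a", 5)), "2 groups")
})

test_that("Brown-Forsythe: examples and exact ANOVA-on-deviations identity", {
  r0 <- brown_forsythe(list(c(1, 2, 3), c(11, 12, 13)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  r <- brown_forsythe(list(c(1, 2, 3, 4), c(0, 4, 8, 12)))
  expect_equal(r$statistic, 6.3529, tolerance = 1e-4)
  expect_equal(r$df, c(1L, 6L))
  expect_equal(r$p, 0.0455, tolerance = 1e-2)
  # identical groups: F = 0
  g <- c(2, 5, 9, 1)
  expect_equal(brown_forsythe(list(g, g, g))$statistic, 0)
  # identity with anova_oneway on |x - median|
  set.seed(32)
  for (i in 1:10) {
    gs <- lapply(1:3, function(k) rnorm(4 + k, sd = k))
    bf <- brown_forsythe(gs)
    dev <- lapply(gs, function(x) abs(x - median(x)))
    ao <- anova_oneway(unlist(dev), rep(1:3, lengths(dev)))
    expect_identical(bf$statistic, ao$statistic)
    expect_identical(bf$p, ao$p)
  }
})

test_that("variance-test p-values are uniform under a simulated null", {
  set.seed(33)
  p_f <- replicate(500, variance_ratio_test(rnorm(12), rnorm(15))$p)
  expect_gt(ks.test(p_f, "punif")$p.value, 0.01)
  p_bf <- replicate(500, {
    x <- rnorm(30)
    brown_forsythe(split(x, rep(1:3, 10)))$p
  })
  expect_gt(ks.test(p_bf, "punif")$p.value, 0.01)
})

test_that("eta-covariate ANOVA detects a true clearance shift only", {
  set.seed(34)
  hits_cl <- 0L; false_vka <- 0L
  for (r in 1:20) {
    n <- 30
    em <- cbind(rnorm(2 * n, rep(c(0, 0.4), each = n), 0.3),
                rnorm(2 * n, 0, 0.3), rnorm(2 * n, 0, 0.3))
    res <- eta_covariate_test(em, rep(c("ref", "trt"), each = n))
    if (res$p[1] < 0.01) hits_cl <- hits_cl + 1L
    if (any(res$p[2:3] < 0.05)) false_vka <- false_vka + 1L
  }
  expect_gte(hits_cl, 18L)
  expect_lte(false_vka, 5L)
  # permuted labels: p roughly uniform
  set.seed(35)
  pp <- replicate(200, {
    em <- cbind(rnorm(40, rep(c(0, 0.4), each = 20), 0.3), rnorm(40),
                rnorm(40))
    eta_covariate_test(em, sample(rep(c("a", "b"), 20)))$p[1]
  })
  expect_gt(ks.test(pp, "punif")$p.value, 0.01)
  # identical etas in all groups
  em0 <- matrix(1, 10, 3)
  expect_equal(eta_covariate_test(em0, rep(c("a", "b"), 5))$p, rep(1, 3))
})

test_that("pearson and spearman: closed-form examples against cor.test", {
  r <- pearson_test(1:10, 2 * (1:10) + 1)
  expect_equal(r$statistic, 1)
  expect_equal(r$p, 0)
  r2 <- pearson_test(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r2$statistic, 0.5)
  expect_equal(r2$p, 2 / 3, tolerance = 1e-10)
  rho <- spearman_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(rho$statistic, 0.6)
  expect_identical(rho$method, "exact")
  expect_equal(rho$p, cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3),
                               method = "spearman")$p.value,
               tolerance = 1e-10)
  set.seed(36)
  x <- rnorm(25); y <- 0.5 * x + rnorm(25)
  rp <- pearson_test(x, y)
  ct <- cor.test(x, y)
  expect_equal(rp$statistic, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(rp$p, ct$p.value, tolerance = 1e-12)
  expect_error(pearson_test(rep(1, 5), rnorm(5)), "constant")
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(37)
  x <- rexp(15); y <- rnorm(15)
  base <- spearman_test(x, y)$statistic
  expect_equal(spearman_test(exp(x), y)$statistic, base)
  expect_equal(spearman_test(x, y^3)$statistic, base)
  expect_equal(spearman_test(log(x), atan(y))$statistic, base)
})

test_that("ddCt fold change arithmetic", {
  expect_equal(ddct_fold_change(24, 20, 25, 20), 2)
  expect_equal(ddct_fold_change(20, 20, 20, 20), 1)
  expect_equal(ddct_fold_change(21, 20, 20, 20), 0.5)
  expect_error(ddct_fold_change(NA, 20, 20, 20), "finite")
})

test_that("group mean AUCs order as the efflux-activity gradient", {
  # ATB < control < ZSQ < ATB+ZSQ, the reported exposure ordering
  ok <- 0L
  for (s in 1:5) {
    sim <- simulate_study(seed = 700 + s)
    gs <- group_auc_summary(sim$truth,
                            groups = c("TAC+ATB", "TAC", "TAC+ZSQ",
                                       "TAC+ATB+ZSQ"))
    if (all(diff(gs$mean) > 0)) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("group AUC summary: hand-computed table and single values", {
  est <- data.frame(group = rep(c("A", "B"), c(4, 1)),
                    auc = c(10, 12, 14, 16, 30))
  gs <- group_auc_summary(est)
  expect_equal(gs$mean, c(13, 30))
  expect_equal(gs$variance[1], var(c(10, 12, 14, 16)))
  expect_true(is.na(gs$variance[2]))
  half <- qt(0.975, 3) * sqrt(var(c(10, 12, 14, 16)) / 4)
  expect_equal(gs$ci_lo[1], 13 - half)
  expect_equal(gs$ci_hi[1], 13 + half)
})
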