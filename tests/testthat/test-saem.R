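# SAEM estimator: validation, identifiability on rich data, sparse-design
# recovery, M-step oracle, determinism, importance-sampling likelihood and
# the likelihood-ratio test. Simulation sizes are scaled for the test
# budget; the full-scale recovery runs live in test-acceptance.R.

fast_cfg <- function(seed, k1 = 120, k2 = 60, n_is = 0)
  saem_config(k1 = k1, k2 = k2, n_is = n_is, seed = seed)

test_that("fit_saem validates its inputs", {
  expect_error(pk_dataset(list(), tau = 24), "at least one")
  one <- pk_dataset(list(pk_subject("a", "G", 100, times = 2, conc = 5)))
  expect_error(fit_saem(one, pk_model_spec(), fast_cfg(1)), "2 subjects")
  flat <- pk_dataset(lapply(1:5, function(i)
    pk_subject(paste0("s", i), "G", 100, times = c(2, 2), conc = c(5, 6))))
  expect_error(fit_saem(flat, pk_model_spec(), fast_cfg(1)),
               "non-identifiable")
})

test_that("near-noiseless rich design recovers theta within 1%", {
  des <- default_paper_design(group_n = c(A = 50),
                              samples_range = c(6L, 6L), p_max = 0, lloq = 0)
  tr <- default_truth(auc_means = c(A = 195.4), omega_cv = 0,
                      error_a = 0.01)
  sim <- simulate_study(des, tr, seed = 11)
  fit <- fit_saem(sim$data, pk_model_spec(covariate = "none"),
                  fast_cfg(11))
  est <- fit$fixed_effects$estimate[1:3]
  expect_equal(est, c(0.32, 1.88, 1.20), tolerance = 0.01)
  # agreement with an independent pooled nonlinear least-squares oracle
  st <- tacropk:::.stack_dataset(sim$data, "m3")
  obj <- function(lp) {
    f <- tacropk:::.css(rep(exp(lp[1]), st$n_obs), exp(lp[2]), exp(lp[3]),
                        st$dose[st$sub], 24, st$t)
    sum((st$y - f)^2)
  }
  nls <- optim(log(c(0.3, 2, 1)), obj, control = list(reltol = 1e-14,
                                                      maxit = 5000))
  expect_equal(est, exp(nls$par), tolerance = 0.01)
})

test_that("sparse paper-like design recovers CL/F within 10%", {
  sim <- simulate_study(seed = 2)
  fit <- fit_saem(sim$data, pk_model_spec(), fast_cfg(2))
  cl <- fit$fixed_effects$estimate[fit$fixed_effects$parameter == "cl_pop"]
  expect_lt(abs(cl - 0.32) / 0.32, 0.10)
  expect_true(all(is.finite(fit$fixed_effects$estimate)))
  expect_true(all(fit$fixed_effects$ci_lo <= fit$fixed_effects$estimate &
                    fit$fixed_effects$estimate <= fit$fixed_effects$ci_hi))
  expect_identical(nrow(fit$trajectories), 180L)
})

test_that("MH acceptance rates adapt into a sane band", {
  sim <- simulate_study(seed = 3)
  fit <- fit_saem(sim$data, pk_model_spec(), fast_cfg(3))
  expect_true(all(fit$acc_rates > 0.1 & fit$acc_rates < 0.6))
})

test_that("identical data, config and seed give identical trajectories", {
  sim <- simulate_study(seed = 5)
  f1 <- fit_saem(sim$data, pk_model_spec(), fast_cfg(7, k1 = 25, k2 = 10))
  f2 <- fit_saem(sim$data, pk_model_spec(), fast_cfg(7, k1 = 25, k2 = 10))
  expect_identical(f1$trajectories, f2$trajectories)
  expect_identical(f1$fixed_effects, f2$fixed_effects)
})

test_that("closed-form M-step maximises the complete-data log-likelihood", {
  # freeze one sampled phi; the M-step must agree with direct numerical
  # maximisation of sum_i log N3(phi_i; mu_i, Omega) + Gaussian error part
  set.seed(13)
  sim <- simulate_study(default_paper_design(
    group_n = c(A = 10, B = 8)), default_truth(
      auc_means = c(A = 195.4, B = 131.1)), seed = 13)
  st <- tacropk:::.stack_dataset(sim$data, "m3")
  N <- st$n_sub
  phi <- cbind(rnorm(N, log(0.32), 0.3), rnorm(N, log(1.88), 0.2),
               rnorm(N, log(1.2), 0.25))
  j <- st$sub
  f <- tacropk:::.css(exp(phi[, 1])[j], exp(phi[, 2])[j], exp(phi[, 3])[j],
                      st$dose[j], 24, st$t)
  r2 <- (st$y - f)^2
  r2[st$cens] <- (st$lloq / 2 - f[st$cens])^2  # arbitrary frozen values
  spec <- pk_model_spec(covariate = "group", omega_structure = "full")
  err <- list(ss_add = sum(r2), ss_prop = sum(r2 / pmax(f, 1e-6)^2),
              f2 = f^2, r2 = r2, n = st$n_obs)
  ms <- tacropk:::.mstep(phi, crossprod(phi), err, st, spec, diag(0.09, 3))
  # oracle: numerical maximisation over (m, chol(Omega))
  negll <- function(par) {
    m <- par[1:4]; Lv <- par[5:10]
    Lm <- matrix(0, 3, 3); Lm[lower.tri(Lm, diag = TRUE)] <- Lv
    O <- tcrossprod(Lm)
    mu <- cbind(m[st$group_idx], rep(m[3], N), rep(m[4], N))
    R <- phi - mu
    oi <- solve(O)
    N / 2 * determinant(O)$modulus[1] + sum((R %*% oi) * R) / 2
  }
  ch <- chol(ms$omega)
  start <- c(ms$m[1:2], ms$m[3:4],
             t(ch)[lower.tri(ch, diag = TRUE)])
  op <- optim(start, negll, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-15))
  expect_lte(negll(start), op$value + 1e-6)
  a_hat <- sqrt(mean(r2))
  expect_equal(ms$a, a_hat, tolerance = 1e-10)
})

test_that("importance-sampling loglik: exact at Omega = 0, matches 1-D quadrature", {
  ds <- toy_dataset()
  m0 <- pk_model(c(cl = 0.32, v = 1.88, ka = 1.2), groups = c("G1", "G2"),
                 beta = c(G2 = 0.2), omega = matrix(0, 3, 3),
                 error_model = "additive", error_params = c(a = 2))
  ll0 <- estimate_loglik_is(ds, m0, n_is_samples = 50, seed = 1)
  direct <- sum(vapply(ds$subjects, function(s)
    loglik_conditional(m0, s, c(0, 0, 0), blq = "exclude"), 0))
  expect_equal(ll0$loglik, direct, tolerance = 1e-6)
  expect_identical(ll0$mc_se, 0)
  # single random effect on cl: adaptive quadrature oracle
  m1 <- pk_model(c(cl = 0.32, v = 1.88, ka = 1.2), groups = c("G1", "G2"),
                 beta = c(G2 = 0.2), omega = diag(c(0.09, 0, 0)),
                 error_model = "additive", error_params = c(a = 2))
  ll1 <- estimate_loglik_is(ds, m1, n_is_samples = 4000, seed = 2)
  quad <- sum(vapply(ds$subjects, function(s) {
    f <- Vectorize(function(e) exp(loglik_conditional(m1, s, c(e, 0, 0),
                                                      blq = "exclude") +
                                     dnorm(e, 0, 0.3, log = TRUE)))
    log(integrate(f, -4, 4, rel.tol = 1e-10)$value)
  }, 0))
  expect_lt(abs(ll1$loglik - quad), 3 * ll1$mc_se + 1e-3)
})

test_that("Monte-Carlo SE shrinks like 1/sqrt(n)", {
  ds <- toy_dataset()
  m <- toy_model("additive", a = 2)
  se_n <- mean(vapply(1:5, function(s)
    estimate_loglik_is(ds, m, 400, seed = s)$mc_se, 0))
  se_2n <- mean(vapply(1:5, function(s)
    estimate_loglik_is(ds, m, 1600, seed = 100 + s)$mc_se, 0))
  expect_gt(se_n / se_2n, 1.5)
  expect_lt(se_n / se_2n, 2.7)
})

test_that("error-model comparison is deterministic and picks proportional truth", {
  des <- default_paper_design(group_n = c(A = 40), lloq = 0.05)
  tr <- pk_model(c(cl = 0.32, v = 1.88, ka = 1.2), groups = "A",
                 omega = diag(0.09, 3), error_model = "proportional",
                 error_params = c(b = 0.2))
  wins <- 0L
  for (s in 1:3) {
    sim <- simulate_study(des, tr, seed = 20 + s)
    cfg <- fast_cfg(20 + s, k1 = 100, k2 = 50, n_is = 300)
    tab <- compare_error_models(sim$data, pk_model_spec(covariate = "none"),
                                cfg)
    expect_identical(sort(tab$rank), 1:3)
    if (tab$error_model[tab$rank == 1] == "proportional") wins <- wins + 1L
  }
  expect_gte(wins, 2L)
  # determinism of the whole table
  sim <- simulate_study(des, tr, seed = 21)
  cfg <- fast_cfg(99, k1 = 20, k2 = 10, n_is = 100)
  t1 <- compare_error_models(sim$data, pk_model_spec(covariate = "none"), cfg)
  t2 <- compare_error_models(sim$data, pk_model_spec(covariate = "none"), cfg)
  attr(t1, "fits") <- attr(t2, "fits") <- NULL
  expect_identical(t1, t2)
})

test_that("likelihood-ratio test arithmetic", {
  f0 <- list(loglik = -100); f1 <- list(loglik = -100)
  r <- lrt(f0, f1, df = 3)
  expect_identical(r$statistic, 0)
  expect_identical(r$p, 1)
  r2 <- lrt(list(loglik = -105), list(loglik = -100), df = 3)
  expect_equal(r2$statistic, 10)
  expect_equal(r2$p, pchisq(10, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(r2$p, 0.0186, tolerance = 1e-2)
  expect_warning(r3 <- lrt(list(loglik = -99), list(loglik = -100), df = 1),
                 "clamped")
  expect_identical(r3$statistic, 0)
})
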