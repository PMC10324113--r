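# Hierarchical layer: exponential covariate/random-effect model, residual
# error models, conditional log-densities.

test_that("model constructor enforces its invariants", {
  expect_error(toy_model(omega = matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)),
               "semidefinite")
  expect_error(pk_model(c(cl = -1, v = 1, ka = 1), groups = "A"), "theta")
  expect_error(pk_model(c(cl = 1, v = 1, ka = 1), groups = c("A", "B"),
                        beta = c(C = 1)), "not in groups")
  expect_error(pk_model(c(cl = 1, v = 1, ka = 1), groups = "A",
                        error_model = "additive", error_params = c(a = 0)),
               "incompatible")
  m <- toy_model()
  expect_identical(m$beta[["G1"]], 0)
})

test_that("individual_params applies the exponential model", {
  m <- toy_model()
  s1 <- pk_subject("x", "G1", 1000)
  p0 <- individual_params(m, s1, c(0, 0, 0))
  expect_equal(unclass(p0)[c("cl", "v", "ka")],
               list(cl = 0.32, v = 1.88, ka = 1.20))
  # printed group AUC ratio 195.4/131.1 as a beta on log-CL
  m2 <- pk_model(c(cl = 0.32, v = 1.88, ka = 1.2),
                 groups = c("TAC", "ATB"), beta = c(ATB = log(195.4 / 131.1)))
  pa <- individual_params(m2, pk_subject("y", "ATB", 1), c(0, 0, 0))
  expect_equal(pa$cl, 0.32 * 195.4 / 131.1, tolerance = 1e-12)
  # monotone scaling in each component
  p2 <- individual_params(m, s1, c(log(2), 0, 0))
  expect_equal(p2$cl, 2 * p0$cl)
  expect_equal(p2$v, p0$v)
  expect_equal(p2$ka, p0$ka)
  set.seed(7)
  for (k in 1:3) {
    etas <- sort(rnorm(5))
    vals <- vapply(etas, function(e) {
      eta <- c(0, 0, 0); eta[k] <- e
      unlist(unclass(individual_params(m, s1, eta)))[k]
    }, 0)
    expect_true(all(diff(vals) > 0))
  }
  expect_error(individual_params(m, pk_subject("z", "nope", 1), c(0, 0, 0)),
               "unknown group")
})

test_that("residual_sd implements the three error models consistently", {
  expect_equal(residual_sd(toy_model("additive", a = 2), 50), 2)
  expect_equal(residual_sd(toy_model("proportional", b = 0.1), 50), 5)
  expect_equal(residual_sd(toy_model("combined", a = 3, b = 0.1), 40), 5)
  # combined degenerates exactly to the pure models
  cp <- seq(0, 80, by = 7)
  expect_equal(residual_sd(toy_model("combined", a = 2, b = 0), cp),
               residual_sd(toy_model("additive", a = 2), cp))
  expect_equal(residual_sd(toy_model("combined", a = 0, b = 0.2), cp),
               residual_sd(toy_model("proportional", b = 0.2), cp))
})

test_that("loglik_conditional matches direct Gaussian arithmetic", {
  m <- toy_model("additive", a = 1)
  empty <- pk_subject("e", "G1", 1000)
  expect_identical(loglik_conditional(m, empty, c(0, 0, 0)), 0)
  # one observation placed exactly at the prediction
  p0 <- individual_params(m, pk_subject("x", "G1", 75000), c(0, 0, 0))
  f2 <- conc_steady_state(p0, 75000, 24, 2)
  s <- pk_subject("x", "G1", 75000, times = 2, conc = f2)
  expect_equal(loglik_conditional(m, s, c(0, 0, 0)), log(1 / sqrt(2 * pi)),
               tolerance = 1e-12)
  # two observations, hand-computed sum
  ma <- toy_model("additive", a = 2)
  s2 <- pk_subject("x", "G1", 75000, times = c(2, 8), conc = c(25, 10))
  f <- conc_steady_state(p0, 75000, 24, c(2, 8))
  byhand <- sum(-log(2 * sqrt(2 * pi)) - (c(25, 10) - f)^2 / (2 * 4))
  expect_equal(loglik_conditional(ma, s2, c(0, 0, 0)), byhand)
})

test_that("BLQ policies alter the conditional likelihood as documented", {
  m <- toy_model("additive", a = 2)
  s <- pk_subject("x", "G1", 75000, times = c(2, 24), conc = c(25, NA),
                  blq = c(FALSE, TRUE))
  p0 <- individual_params(m, pk_subject("x", "G1", 75000), c(0, 0, 0))
  f <- conc_steady_state(p0, 75000, 24, c(2, 24))
  ll_1 <- dnorm(25, f[1], 2, log = TRUE)
  expect_equal(loglik_conditional(m, s, c(0, 0, 0), blq = "exclude"), ll_1)
  expect_equal(loglik_conditional(m, s, c(0, 0, 0), blq = "loq2"),
               ll_1 + dnorm(0.25, f[2], 2, log = TRUE))
  expect_equal(loglik_conditional(m, s, c(0, 0, 0), blq = "m3"),
               ll_1 + pnorm(0.5, f[2], 2, log.p = TRUE))
})

test_that("logprior_eta closed forms, singular support and mode at zero", {
  expect_equal(logprior_eta(diag(3), c(0, 0, 0)), -3 / 2 * log(2 * pi))
  expect_equal(logprior_eta(diag(0.09, 3), c(0, 0, 0)),
               -3 / 2 * log(2 * pi) - 3 / 2 * log(0.09))
  om <- diag(c(0.09, 0, 0))
  expect_equal(logprior_eta(om, c(0.1, 0, 0)),
               dnorm(0.1, 0, 0.3, log = TRUE))
  expect_identical(logprior_eta(om, c(0.1, 0.2, 0)), -Inf)
  set.seed(5)
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3)
    om <- crossprod(A) + diag(0.01, 3)
    e <- rnorm(3, sd = 0.5)
    expect_lte(logprior_eta(om, e), logprior_eta(om, c(0, 0, 0)))
  }
})

test_that("conditional posterior is integrable on a 1-D random-effect toy", {
  m <- toy_model("additive", a = 2, omega = diag(c(0.09, 0, 0)))
  s <- pk_subject("x", "G1", 75000, times = c(2, 8), conc = c(25, 10))
  dens <- Vectorize(function(e1)
    exp(loglik_conditional(m, s, c(e1, 0, 0)) +
          dnorm(e1, 0, 0.3, log = TRUE)))
  z <- integrate(dens, -3, 3, rel.tol = 1e-9)
  expect_true(is.finite(z$value) && z$value > 0)
})
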