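# Independent oracles used by the unit tests. These deliberately do not
# share code with the package: RK4 integration of the gut/central linear
# ODE system, trapezoidal quadrature, and brute-force grid searches.

# RK4 integration of a' = -ka a ; c' = ka a / v - (cl/v) c with bolus doses
# of `dose` ng into the gut compartment every tau h. Returns central
# concentration (ng/mL) at time t since the first dose.
ode_conc_oracle <- function(cl, v, ka, dose, tau, n_doses, t, dt = 0.001) {
  ke <- cl / v
  deriv <- function(state) c(-ka * state[1], ka * state[1] / v - ke * state[2])
  state <- c(dose, 0)  # first dose at time 0
  dose_times <- (seq_len(n_doses) - 1) * tau
  tcur <- 0
  while (tcur < t - 1e-12) {
    h <- min(dt, t - tcur)
    k1 <- deriv(state)
    k2 <- deriv(state + h / 2 * k1)
    k3 <- deriv(state + h / 2 * k2)
    k4 <- deriv(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    tcur <- tcur + h
    hit <- which(abs(dose_times - tcur) < 1e-9 & dose_times > 0)
    if (length(hit)) state[1] <- state[1] + dose
  }
  state[2] / 1000
}

# trapezoid integral of f on [lo, hi] with n points
trapz_oracle <- function(f, lo, hi, n = 1e5) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# random valid structural parameters (ka > ke), reproducible by caller seed
random_params <- function() {
  cl <- runif(1, 0.1, 1)
  v <- runif(1, 0.5, 4)
  ke <- cl / v
  ka <- ke * runif(1, 1.5, 20)
  pk_params(cl = cl, v = v, ka = ka)
}

# small deterministic two-group dataset for plumbing tests
toy_dataset <- function() {
  s1 <- pk_subject("s1", "G1", dose = 75000, times = c(1, 2, 8),
                   conc = c(25, 30, 14), blq = c(FALSE, FALSE, FALSE))
  s2 <- pk_subject("s2", "G1", dose = 80000, times = c(2, 6, 24),
                   conc = c(33, 20, NA), blq = c(FALSE, FALSE, TRUE))
  s3 <- pk_subject("s3", "G2", dose = 70000, times = c(1, 4),
                   conc = c(20, 22), blq = c(FALSE, FALSE))
  pk_dataset(list(s1, s2, s3), tau = 24, groups = c("G1", "G2"), lloq = 0.5)
}

toy_model <- function(error_model = "additive", a = 2, b = 0.1,
                      omega = diag(0.09, 3)) {
  pk_model(theta = c(cl = 0.32, v = 1.88, ka = 1.20),
           groups = c("G1", "G2"), beta = c(G2 = 0.2), omega = omega,
           error_model = error_model, error_params = c(a = a, b = b))
}
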