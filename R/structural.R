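# One-compartment oral model with first-order absorption and elimination.
# All internal computation is in ng and L (so ng/L); conversion to ng/mL
# happens once, at the public boundary (/ 1000).

#' Structural one-compartment PK parameters
#'
#' Container for the individual-level parameter triple of the oral
#' one-compartment model: apparent clearance `CL/F` (L/h), apparent volume
#' of distribution `V/F` (L) and first-order absorption rate constant `Ka`
#' (1/h). The elimination rate constant `Ke = CL/V` is derived.
#'
#' @param cl Apparent oral clearance CL/F, L/h. Must be > 0.
#' @param v Apparent volume of distribution V/F, L. Must be > 0.
#' @param ka First-order absorption rate constant, 1/h. Must be > 0.
#' @return An object of class `pk_params`.
#' @examples
#' p <- pk_params(cl = 0.32, v = 1.88, ka = 1.20)
#' half_life(p)
#' @export
pk_params <- function(cl, v, ka) {
  for (nm in c("cl", "v", "ka")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("'", nm, "' must be a single finite positive number", call. = FALSE)
  }
  structure(list(cl = cl, v = v, ka = ka), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("pk_params: CL/F = %.4g L/h, V = %.4g L, Ka = %.4g 1/h (Ke = %.4g 1/h)\n",
              x$cl, x$v, x$ka, x$cl / x$v))
  invisible(x)
}

# Vectorised steady-state concentration kernel, ng/mL.  All of cl, v, ka,
# dose, t may be vectors (recycled); tau is scalar.  Used by the estimation
# machinery where per-observation parameter vectors are the common case.
.css <- function(cl, v, ka, dose, tau, t) {
  ke <- cl / v
  degen <- abs(ka - ke) < 1e-8 * ke
  out <- numeric(length(ke + ka + dose + t))
  e_ke <- exp(-ke * t)
  if (any(!degen)) {
    c1 <- dose * ka / (v * (ka - ke))
    out[!degen] <- (c1 * (e_ke / (1 - exp(-ke * tau)) -
                          exp(-ka * t) / (1 - exp(-ka * tau))))[!degen]
  }
  if (any(degen)) {
    # ka -> ke limit of the steady-state form (analytic derivative in ka)
    E <- exp(-ke * tau)
    out[degen] <- (dose * ke / v * e_ke * (t * (1 - E) + tau * E) / (1 - E)^2)[degen]
  }
  pmax(out, 0) / 1000
}

# Single-dose concentration (ng/mL) at time s >= 0 after one dose.
.c1 <- function(cl, v, ka, dose, s) {
  ke <- cl / v
  degen <- abs(ka - ke) < 1e-8 * ke
  out <- numeric(length(ke + s))
  if (any(!degen))
    out[!degen] <- (dose * ka / (v * (ka - ke)) * (exp(-ke * s) - exp(-ka * s)))[!degen]
  if (any(degen))
    out[degen] <- (dose * ke / v * s * exp(-ke * s))[degen]
  pmax(out, 0) / 1000
}

#' Steady-state concentration under repeated oral dosing
#'
#' Closed-form whole-blood concentration at steady state for a dose given
#' every `tau` hours:
#' \deqn{C_{ss}(t) = \frac{D\,K_a}{V (K_a - K_e)}\left[
#'   \frac{e^{-K_e t}}{1 - e^{-K_e \tau}} -
#'   \frac{e^{-K_a t}}{1 - e^{-K_a \tau}}\right]}
#' with `t` the time since the last dose. When `|Ka - Ke| < 1e-8 Ke` the
#' analytic limit branch is taken to avoid catastrophic cancellation.
#'
#' @param p A [pk_params()] object.
#' @param dose Dose amount per administration, ng.
#' @param tau Dosing interval, h.
#' @param t Time since last dose, h; vectorised; must lie in `[0, tau]`.
#' @return Concentration(s) in ng/mL.
#' @export
conc_steady_state <- function(p, dose, tau, t) {
  stopifnot(inherits(p, "pk_params"))
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0)
    stop("'dose' must be a single nonnegative number (ng)", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a single positive number (h)", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0) || any(t > tau))
    stop("'t' must lie within [0, tau]", call. = FALSE)
  if (dose == 0) return(numeric(length(t)) + 0)
  .css(p$cl, p$v, p$ka, dose, tau, t)
}

#' Concentration after a finite number of repeated doses
#'
#' Superposition of single-dose curves for every dose already administered
#' at time `t` since the first dose (doses at `0, tau, ..., (n_doses-1) tau`).
#' Converges to [conc_steady_state()] as `n_doses` grows.
#'
#' @inheritParams conc_steady_state
#' @param n_doses Number of administered doses (>= 1).
#' @param t Time since the *first* dose, h; vectorised, `t >= 0`.
#' @return Concentration(s) in ng/mL.
#' @export
conc_multidose <- function(p, dose, tau, n_doses, t) {
  stopifnot(inherits(p, "pk_params"))
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0)
    stop("'dose' must be a single nonnegative number (ng)", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a single positive number (h)", call. = FALSE)
  if (!is.numeric(n_doses) || length(n_doses) != 1L || n_doses < 1)
    stop("'n_doses' must be >= 1", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be nonnegative (time since first dose)", call. = FALSE)
  if (dose == 0) return(numeric(length(t)) + 0)
  out <- numeric(length(t))
  for (j in seq_len(n_doses)) {
    s <- t - (j - 1) * tau
    given <- s >= 0
    if (any(given)) out[given] <- out[given] + .c1(p$cl, p$v, p$ka, dose, s[given])
  }
  out
}

#' Elimination half-life
#'
#' @param p A [pk_params()] object.
#' @return `ln(2) * V / CL`, hours.
#' @export
half_life <- function(p) {
  stopifnot(inherits(p, "pk_params"))
  log(2) * p$v / p$cl
}

#' Steady-state AUC over one dosing interval
#'
#' At steady state the area under the concentration-time curve over one
#' dosing interval equals `dose / CL` (independent of `V` and `Ka`).
#'
#' @param p A [pk_params()] object.
#' @param dose Dose amount per administration, ng.
#' @return AUC over the interval, ng.h/mL.
#' @export
auc_tau <- function(p, dose) {
  stopifnot(inherits(p, "pk_params"))
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0)
    stop("'dose' must be a single nonnegative number (ng)", call. = FALSE)
  dose / p$cl / 1000
}

#' Time of the single-dose concentration peak
#'
#' `Tmax = log(Ka/Ke) / (Ka - Ke)`, with the limit `1/Ke` when `Ka == Ke`.
#'
#' @param p A [pk_params()] object.
#' @return Time of maximum concentration after a single dose, h.
#' @export
tmax_single_dose <- function(p) {
  ke <- p$cl / p$v
  if (abs(p$ka - ke) < 1e-8 * ke) return(1 / ke)
  log(p$ka / ke) / (p$ka - ke)
}
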