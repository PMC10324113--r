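# Hierarchical population layer: typical values, group covariates on
# log-clearance, log-normal random effects, residual-error models and the
# conditional densities consumed by SAEM and empirical-Bayes estimation.
# The random-effect order is fixed everywhere as (log-CL, log-V, log-Ka).

#' Population PK model
#'
#' Fixed effects (typical values), treatment-group covariate coefficients on
#' log-clearance, the random-effect covariance matrix and a residual-error
#' model. Between-subject variability is exponential: individual parameters
#' are log-normal around the group-specific typical value.
#'
#' @param theta Named numeric `c(cl=, v=, ka=)`: typical CL/F (L/h),
#'   V (L) and Ka (1/h); all > 0.
#' @param groups Character vector of treatment-group labels; the first is
#'   the reference group.
#' @param beta Named numeric of additive effects on log(CL) per group. The
#'   reference group's coefficient must be 0 (it is filled in when absent).
#' @param omega 3x3 symmetric positive semidefinite covariance of the random
#'   effects, order (log-cl, log-v, log-ka).
#' @param error_model One of `"additive"`, `"proportional"`, `"combined"`.
#' @param error_params Named numeric `c(a=, b=)`: additive SD `a` (ng/mL) and
#'   proportional coefficient `b` (unitless). `a >= 0`, `b >= 0`, `a + b > 0`
#'   for the components the error model uses.
#' @return An object of class `pk_model`.
#' @examples
#' m <- pk_model(theta = c(cl = 0.32, v = 1.88, ka = 1.20),
#'               groups = c("TAC", "TAC+ATB"),
#'               beta = c("TAC+ATB" = log(195.4 / 131.1)),
#'               omega = diag(0.09, 3),
#'               error_model = "additive", error_params = c(a = 2))
#' @export
pk_model <- function(theta, groups, beta = NULL, omega = diag(0.09, 3),
                     error_model = c("additive", "proportional", "combined"),
                     error_params = c(a = 2, b = 0)) {
  error_model <- match.arg(error_model)
  if (is.null(names(theta))) names(theta) <- c("cl", "v", "ka")
  theta <- theta[c("cl", "v", "ka")]
  if (any(!is.finite(theta)) || any(theta <= 0))
    stop("all components of 'theta' must be finite and > 0", call. = FALSE)
  groups <- as.character(groups)
  if (anyDuplicated(groups)) stop("duplicate group labels", call. = FALSE)
  full_beta <- stats::setNames(numeric(length(groups)), groups)
  if (!is.null(beta)) {
    if (is.null(names(beta))) stop("'beta' must be named by group", call. = FALSE)
    unknown <- setdiff(names(beta), groups)
    if (length(unknown))
      stop("beta names not in groups: ", paste(unknown, collapse = ", "), call. = FALSE)
    full_beta[names(beta)] <- beta
  }
  if (full_beta[[1L]] != 0)
    stop("the reference group (first of 'groups') must have beta = 0", call. = FALSE)
  omega <- as.matrix(omega)
  if (!isTRUE(all.equal(dim(omega), c(3L, 3L))) ||
      max(abs(omega - t(omega))) > 1e-10)
    stop("'omega' must be a symmetric 3x3 matrix", call. = FALSE)
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("'omega' must be positive semidefinite", call. = FALSE)
  a <- if ("a" %in% names(error_params)) unname(error_params[["a"]]) else 0
  b <- if ("b" %in% names(error_params)) unname(error_params[["b"]]) else 0
  if (a < 0 || b < 0) stop("error parameters must be >= 0", call. = FALSE)
  needs <- switch(error_model, additive = a > 0, proportional = b > 0,
                  combined = a + b > 0)
  if (!needs)
    stop("error parameters incompatible with error model '", error_model, "'",
         call. = FALSE)
  structure(list(theta = theta, groups = groups, beta = full_beta,
                 omega = omega, error_model = error_model,
                 error_params = c(a = a, b = b)),
            class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("Population PK model (one-compartment oral, steady state)\n")
  cat(sprintf("  theta: CL/F = %.4g L/h, V = %.4g L, Ka = %.4g 1/h\n",
              x$theta[["cl"]], x$theta[["v"]], x$theta[["ka"]]))
  cat("  groups:", paste(x$groups, collapse = ", "),
      sprintf("(reference: %s)\n", x$groups[1L]))
  nz <- x$beta[x$beta != 0]
  if (length(nz))
    cat("  beta on log-CL:",
        paste(sprintf("%s=%+.3f", names(nz), nz), collapse = ", "), "\n")
  cat(sprintf("  omega SDs: %.3f %.3f %.3f (log-cl, log-v, log-ka)\n",
              sqrt(x$omega[1, 1]), sqrt(x$omega[2, 2]), sqrt(x$omega[3, 3])))
  cat(sprintf("  error: %s (a = %.3g ng/mL, b = %.3g)\n", x$error_model,
              x$error_params[["a"]], x$error_params[["b"]]))
  invisible(x)
}

#' Single study subject
#'
#' @param id Subject identifier (string).
#' @param group Treatment-group label.
#' @param dose Administered dose per interval, ng.
#' @param times Observation times since last dose, h.
#' @param conc Observed concentrations, ng/mL (`NA` allowed where `blq`).
#' @param blq Logical below-LLOQ flags, same length as `times`.
#' @param body_weight Optional body weight, g (used by the simulator).
#' @return An object of class `pk_subject`.
#' @export
pk_subject <- function(id, group, dose, times = numeric(), conc = numeric(),
                       blq = logical(length(times)), body_weight = NA_real_) {
  stopifnot(length(times) == length(conc), length(times) == length(blq))
  if (any(!is.finite(times)) || any(times < 0))
    stop("observation times must be finite and >= 0", call. = FALSE)
  if (!is.numeric(dose) || dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (any(!blq & (!is.finite(conc) | conc < 0)))
    stop("non-BLQ concentrations must be finite and >= 0", call. = FALSE)
  structure(list(id = as.character(id), group = as.character(group),
                 dose = dose, body_weight = body_weight,
                 times = as.numeric(times), conc = as.numeric(conc),
                 blq = as.logical(blq)),
            class = "pk_subject")
}

#' Population PK dataset
#'
#' The unit of all fitting: a list of subjects plus the dosing interval, the
#' ordered set of group labels (first label = reference) and the assay LLOQ.
#'
#' @param subjects List of [pk_subject()] objects with unique ids.
#' @param tau Dosing interval, h.
#' @param groups Ordered group labels; defaults to order of appearance.
#' @param lloq Lower limit of quantification, ng/mL.
#' @return An object of class `pk_dataset`.
#' @export
pk_dataset <- function(subjects, tau = 24, groups = NULL, lloq = 0.5) {
  stopifnot(is.list(subjects), all(vapply(subjects, inherits, TRUE, "pk_subject")))
  ids <- vapply(subjects, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  if (!sum(vapply(subjects, function(s) length(s$times), 0L)))
    stop("dataset must contain at least one observation", call. = FALSE)
  seen <- unique(vapply(subjects, `[[`, "", "group"))
  if (is.null(groups)) groups <- seen
  if (length(setdiff(seen, groups)))
    stop("subject group(s) not in declared groups: ",
         paste(setdiff(seen, groups), collapse = ", "), call. = FALSE)
  bad <- vapply(subjects, function(s) any(s$times > tau), TRUE)
  if (any(bad))
    stop("observation times exceed tau for subject(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  structure(list(subjects = subjects, tau = tau, groups = as.character(groups),
                 lloq = lloq),
            class = "pk_dataset")
}

#' @export
print.pk_dataset <- function(x, ...) {
  n_obs <- sum(vapply(x$subjects, function(s) length(s$times), 0L))
  n_blq <- sum(vapply(x$subjects, function(s) sum(s$blq), 0L))
  cat(sprintf("pk_dataset: %d subjects, %d observations (%d BLQ), tau = %g h, LLOQ = %g ng/mL\n",
              length(x$subjects), n_obs, n_blq, x$tau, x$lloq))
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}

#' Individual structural parameters from the population model
#'
#' Applies the exponential between-subject model:
#' `cl_i = cl_pop * exp(beta[group] + eta1)`, `v_i = v_pop * exp(eta2)`,
#' `ka_i = ka_pop * exp(eta3)`.
#'
#' @param model A [pk_model()].
#' @param subject A [pk_subject()] (only its group label is used).
#' @param eta Numeric 3-vector of random effects (log-cl, log-v, log-ka).
#' @return A [pk_params()] object.
#' @export
individual_params <- function(model, subject, eta = c(0, 0, 0)) {
  stopifnot(inherits(model, "pk_model"), inherits(subject, "pk_subject"))
  if (length(eta) != 3L || any(!is.finite(eta)))
    stop("'eta' must be a finite 3-vector", call. = FALSE)
  if (!subject$group %in% model$groups)
    stop("unknown group label: ", subject$group, call. = FALSE)
  b <- model$beta[[subject$group]]
  pk_params(cl = model$theta[["cl"]] * exp(b + eta[1L]),
            v  = model$theta[["v"]]  * exp(eta[2L]),
            ka = model$theta[["ka"]] * exp(eta[3L]))
}

#' Residual-error standard deviation
#'
#' @param model A [pk_model()].
#' @param c_pred Predicted concentration(s), ng/mL (>= 0).
#' @return SD(s) of the residual error, ng/mL: `a` (additive),
#'   `b * c_pred` (proportional) or `sqrt(a^2 + b^2 c_pred^2)` (combined).
#' @export
residual_sd <- function(model, c_pred) {
  stopifnot(inherits(model, "pk_model"))
  if (any(c_pred < 0)) stop("'c_pred' must be >= 0", call. = FALSE)
  a <- model$error_params[["a"]]; b <- model$error_params[["b"]]
  switch(model$error_model,
         additive = rep_len(a, length(c_pred)),
         proportional = b * c_pred,
         combined = sqrt(a^2 + b^2 * c_pred^2))
}

# Internal vectorised residual SD from (model_name, a, b).
.resid_sd <- function(error_model, a, b, f) {
  switch(error_model,
         additive = rep_len(a, length(f)),
         proportional = b * f,
         combined = sqrt(a^2 + b^2 * f^2))
}

#' Conditional log-likelihood of a subject's observations
#'
#' Gaussian observation model around the steady-state structural prediction
#' at the subject's individual parameters. Below-LLOQ records are handled by
#' `blq`: excluded from the likelihood (default), imputed at `lloq/2`, or
#' treated as left-censored (M3, normal CDF contribution).
#'
#' @inheritParams individual_params
#' @param tau Dosing interval, h.
#' @param lloq Lower limit of quantification, ng/mL (used by the
#'   `"loq2"` and `"m3"` policies).
#' @param blq BLQ policy: `"exclude"`, `"loq2"` or `"m3"`.
#' @return Scalar log-density (0 for a subject without usable observations).
#' @export
loglik_conditional <- function(model, subject, eta, tau = 24, lloq = 0.5,
                               blq = c("exclude", "loq2", "m3")) {
  blq <- match.arg(blq)
  if (length(subject$times) == 0L) return(0)
  p <- individual_params(model, subject, eta)
  y <- subject$conc; t <- subject$times; cens <- subject$blq
  if (blq == "exclude") {
    keep <- !cens
    if (!any(keep)) return(0)
    y <- y[keep]; t <- t[keep]; cens <- cens[keep]
  } else if (blq == "loq2") {
    y[cens] <- lloq / 2
    cens[] <- FALSE
  }
  f <- conc_steady_state(p, subject$dose, tau, t)
  g <- residual_sd(model, f)
  ll <- numeric(length(y))
  obs <- !cens
  ll[obs] <- stats::dnorm(y[obs], f[obs], g[obs], log = TRUE)
  if (any(cens))
    ll[cens] <- stats::pnorm(lloq, f[cens], g[cens], log.p = TRUE)
  sum(ll)
}

#' Log-density of the random-effect prior
#'
#' Multivariate normal `N(0, omega)` log-density, defined on the support of
#' `omega` when it is singular (components in the null space must be 0,
#' otherwise the density is `-Inf`). With `omega = 0` the support is the
#' origin and the log-density is 0 there.
#'
#' @param omega 3x3 PSD covariance matrix.
#' @param eta Numeric 3-vector.
#' @return Scalar log-density.
#' @export
logprior_eta <- function(omega, eta) {
  omega <- as.matrix(omega)
  if (length(eta) != ncol(omega)) stop("dimension mismatch", call. = FALSE)
  ed <- eigen(omega, symmetric = TRUE)
  tol <- 1e-12 * max(abs(ed$values), 1)
  pos <- ed$values > tol
  z <- drop(crossprod(ed$vectors, eta))
  if (any(abs(z[!pos]) > 1e-8)) return(-Inf)
  if (!any(pos)) return(0)
  r <- sum(pos)
  -r / 2 * log(2 * pi) - sum(log(ed$values[pos])) / 2 -
    sum(z[pos]^2 / ed$values[pos]) / 2
}
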