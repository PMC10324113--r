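# Empirical-Bayes conditional modes of the individual random effects and
# the derived individual exposures (AUC over one interval, half-life).

#' Conditional mode of a subject's random effects
#'
#' Maximum of the conditional posterior `loglik + logprior` over eta, found
#' by quasi-Newton with Newton polishing from multiple starts: the prior
#' mode 0 and, when `refine_mcmc`, the best state of a short MCMC run
#' (guards the flip-flop multimodality of sparse subjects). The search runs
#' in the support coordinates of Omega, so a singular Omega (including
#' `Omega = 0`) pins the corresponding components at 0.
#'
#' @param model A [pk_model()].
#' @param subject A [pk_subject()].
#' @param refine_mcmc Add an MCMC-derived second start. Default `TRUE`.
#' @param seed Integer seed for the MCMC start.
#' @param tau Dosing interval, h.
#' @param lloq Assay lower limit of quantification, ng/mL.
#' @param blq BLQ policy (see [loglik_conditional()]).
#' @return Numeric 3-vector `eta_hat`, with attributes `log_posterior` and
#'   `grad_norm`. A subject without usable observations returns the prior
#'   mode `c(0, 0, 0)`.
#' @export
conditional_mode <- function(model, subject, refine_mcmc = TRUE, seed = NULL,
                             tau = 24, lloq = 0.5,
                             blq = c("exclude", "loq2", "m3")) {
  stopifnot(inherits(model, "pk_model"), inherits(subject, "pk_subject"))
  blq <- match.arg(blq)
  ds <- pk_dataset(list(subject, .dummy_subject(subject)), tau = tau,
                   groups = model$groups, lloq = lloq)
  stack <- .stack_dataset(ds, blq)
  sv <- .subject_view(stack, 1L)
  tg <- .subject_target(model, sv, tau, lloq)
  if (tg$r == 0L || sv$n == 0L) {
    out <- c(0, 0, 0)
    attr(out, "log_posterior") <- tg$lp(numeric(tg$r))
    attr(out, "grad_norm") <- 0
    return(out)
  }
  starts <- list(numeric(tg$r))
  if (isTRUE(refine_mcmc)) {
    if (!is.null(seed)) set.seed(seed)
    z <- numeric(tg$r); lp <- tg$lp(z)
    z_best <- z; lp_best <- lp
    sc <- 0.5 * sqrt(tg$lam)
    for (it in 1:200) {
      for (cc in seq_len(tg$r)) {
        z_new <- z; z_new[cc] <- z[cc] + sc[cc] * stats::rnorm(1)
        lp_new <- tg$lp(z_new)
        if (log(stats::runif(1)) < lp_new - lp) { z <- z_new; lp <- lp_new }
        if (lp > lp_best) { z_best <- z; lp_best <- lp }
      }
    }
    starts <- c(starts, list(z_best))
  }
  cm <- .cond_mode_z(tg, starts)
  if (cm$grad_norm >= 1e-6) {
    cond <- structure(class = c("tacropk_ebe_error", "error", "condition"),
                      list(message = sprintf(
                        "conditional-mode search did not converge (gradient norm %.3g) for subject %s",
                        cm$grad_norm, subject$id),
                        call = sys.call(), best = drop(tg$Q %*% cm$z),
                        grad_norm = cm$grad_norm))
    stop(cond)
  }
  out <- drop(tg$Q %*% cm$z)
  attr(out, "log_posterior") <- cm$value
  attr(out, "grad_norm") <- cm$grad_norm
  out
}

# pk_dataset requires >= 1 observation overall and conditional_mode must
# also work for a subject with none; pad with a throwaway companion.
.dummy_subject <- function(subject) {
  pk_subject(id = paste0(subject$id, ".pad"), group = subject$group,
             dose = subject$dose, times = 1, conc = 1, blq = FALSE)
}

#' Individual estimate: parameters and derived exposures
#'
#' @param model A [pk_model()].
#' @param subject A [pk_subject()].
#' @param eta_hat Conditional-mode eta 3-vector.
#' @param tau Dosing interval, h.
#' @return An object of class `pk_individual`: subject id and group, eta,
#'   the individual [pk_params()], `auc_tau = dose / cl_i / 1000`
#'   (ng.h/mL) and `t_half = ln 2 * v_i / cl_i` (h).
#' @export
derive_individual <- function(model, subject, eta_hat, tau = 24) {
  psi <- individual_params(model, subject, eta_hat)
  structure(list(id = subject$id, group = subject$group,
                 eta_hat = as.numeric(eta_hat), params = psi,
                 auc_tau = auc_tau(psi, subject$dose),
                 t_half = half_life(psi), tau = tau),
            class = "pk_individual")
}

#' @export
print.pk_individual <- function(x, ...) {
  cat(sprintf("subject %s [%s]: CL/F = %.3g, V = %.3g, Ka = %.3g | AUC = %.1f ng.h/mL, T1/2 = %.2f h\n",
              x$id, x$group, x$params$cl, x$params$v, x$params$ka,
              x$auc_tau, x$t_half))
  invisible(x)
}

#' Empirical-Bayes estimates for every subject
#'
#' @param fit A `pk_fit` (or a [pk_model()]).
#' @param data The [pk_dataset()] the model was fitted to.
#' @param refine_mcmc Passed to [conditional_mode()].
#' @param seed Integer seed.
#' @return Data frame with one row per subject: `id`, `group`, `dose_ng`,
#'   `eta_cl`, `eta_v`, `eta_ka`, `cl`, `v`, `ka`, `auc`, `t_half`.
#' @export
ebe_estimates <- function(fit, data, refine_mcmc = TRUE, seed = NULL) {
  model <- if (inherits(fit, "pk_fit")) fit$model else fit
  blq <- if (inherits(fit, "pk_fit")) fit$spec$blq else "m3"
  rows <- lapply(seq_along(data$subjects), function(i) {
    s <- data$subjects[[i]]
    eh <- conditional_mode(model, s, refine_mcmc = refine_mcmc,
                           seed = .child_seed(seed, i), tau = data$tau,
                           lloq = data$lloq, blq = blq)
    ind <- derive_individual(model, s, eh, tau = data$tau)
    data.frame(id = s$id, group = s$group, dose_ng = s$dose,
               eta_cl = eh[1L], eta_v = eh[2L], eta_ka = eh[3L],
               cl = ind$params$cl, v = ind$params$v, ka = ind$params$ka,
               auc = ind$auc_tau, t_half = ind$t_half,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Eta shrinkage
#'
#' `1 - SD(eta_hat_k) / sqrt(Omega_kk)` per random-effect component; near 0
#' for rich designs, approaching 1 as the individual data stop informing
#' the etas (sparse designs).
#'
#' @param estimates Data frame from [ebe_estimates()] (columns `eta_cl`,
#'   `eta_v`, `eta_ka`) or a numeric matrix with 3 columns.
#' @param model The [pk_model()] providing Omega.
#' @return Named numeric 3-vector; `NA` where `Omega_kk = 0`.
#' @export
eta_shrinkage <- function(estimates, model) {
  em <- if (is.data.frame(estimates))
    as.matrix(estimates[, c("eta_cl", "eta_v", "eta_ka")])
  else as.matrix(estimates)
  if (nrow(em) < 2L) stop("need at least 2 subjects", call. = FALSE)
  od <- diag(model$omega)
  out <- ifelse(od > 0, 1 - apply(em, 2, stats::sd) / sqrt(od), NA_real_)
  stats::setNames(out, c("eta_cl", "eta_v", "eta_ka"))
}
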