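# SAEM estimation of the population model. E-step: component-wise random
# walk Metropolis-Hastings on each subject's eta targeting the conditional
# posterior. SA step: smoothing of the complete-data sufficient statistics
# with step gamma_k = 1 during burn-in and 1/(k - k1)^a afterwards. M-step:
# closed form (GLS for the fixed effects with full Omega, moment update for
# Omega, closed-form additive / proportional error, small 2-D optimisation
# for the combined error). Standard errors by a stochastic approximation of
# the observed Fisher information (Louis' identity) accumulated during the
# smoothing phase.

#' Model skeleton for estimation
#'
#' Structural choices fed to [fit_saem()]: which residual-error model to
#' estimate, whether the treatment group enters log-CL, the Omega structure
#' and the BLQ policy. The numeric values are estimated.
#'
#' @param error_model `"additive"`, `"proportional"` or `"combined"`.
#' @param covariate `"group"` (per-group effects on log-CL, reference =
#'   first declared group) or `"none"`.
#' @param omega_structure `"full"` (all covariances) or `"diagonal"`.
#' @param constrain_ka_gt_ke Keep `Ka > Ke` at the individual level during
#'   sampling (flip-flop identifiability guard). Default `TRUE`.
#' @param blq Below-LLOQ policy for estimation: `"m3"` (default; censored
#'   likelihood with Gibbs imputation of the latent censored values in the
#'   sufficient statistics), `"exclude"` or `"loq2"`. Exclusion biases the
#'   absorption/terminal parameters at this design because the trough sits
#'   near the LLOQ.
#' @return An object of class `pk_model_spec`.
#' @export
pk_model_spec <- function(error_model = c("additive", "proportional", "combined"),
                          covariate = c("group", "none"),
                          omega_structure = c("full", "diagonal"),
                          constrain_ka_gt_ke = TRUE,
                          blq = c("m3", "exclude", "loq2")) {
  structure(list(error_model = match.arg(error_model),
                 covariate = match.arg(covariate),
                 omega_structure = match.arg(omega_structure),
                 constrain_ka_gt_ke = isTRUE(constrain_ka_gt_ke),
                 blq = match.arg(blq)),
            class = "pk_model_spec")
}

#' SAEM configuration
#'
#' @param k1 Exploratory (burn-in) iterations, step size 1.
#' @param k2 Smoothing iterations, step size `1/(k - k1)^step_exponent`.
#' @param n_chains Number of MCMC chains per subject.
#' @param sweeps Metropolis-Hastings sweeps per iteration.
#' @param proposal_scale Initial random-walk SD per eta component; adapted
#'   towards `accept_target` during the exploratory phase only.
#' @param step_exponent Exponent of the smoothing step-size schedule.
#' @param accept_target Target MH acceptance rate for adaptation.
#' @param convergence_window Trailing iterations inspected for the
#'   convergence flag.
#' @param n_is Importance-sampling draws per subject for the final marginal
#'   log-likelihood (0 skips it).
#' @param anneal Maximum per-iteration shrink factor of the variance
#'   components during the exploratory phase (guards premature collapse of
#'   Omega and the residual variance); set to 0 to disable.
#' @param seed Integer seed controlling all randomness of the fit.
#' @return An object of class `saem_config`.
#' @export
saem_config <- function(k1 = 300, k2 = 100, n_chains = 1, sweeps = 3,
                        proposal_scale = c(0.4, 0.4, 0.4), step_exponent = 1,
                        accept_target = 0.3, convergence_window = 50,
                        n_is = 500, anneal = 0.95, seed = NULL) {
  stopifnot(k1 >= 1, k2 >= 1, n_chains >= 1, sweeps >= 1,
            all(proposal_scale > 0), step_exponent > 0.5, step_exponent <= 1)
  structure(list(k1 = as.integer(k1), k2 = as.integer(k2),
                 n_chains = as.integer(n_chains), sweeps = as.integer(sweeps),
                 proposal_scale = rep_len(proposal_scale, 3L),
                 step_exponent = step_exponent, accept_target = accept_target,
                 convergence_window = as.integer(convergence_window),
                 n_is = as.integer(n_is), anneal = anneal, seed = seed),
            class = "saem_config")
}

# PD inverse with eigenvalue floor; returns list(inv, logdet).
.pd_inv <- function(omega, floor = 1e-10) {
  ed <- eigen(omega, symmetric = TRUE)
  lam <- pmax(ed$values, floor)
  list(inv = ed$vectors %*% (t(ed$vectors) / lam), logdet = sum(log(lam)),
       lam = lam, vec = ed$vectors)
}

# Closed-form M-step given smoothed sufficient statistics.
#   s_phi: N x 3 smoothed individual log-parameters
#   s_S2:  3 x 3 smoothed sum of phi phi'
#   err:   list(ss_add, ss_prop, f2, r2, n) smoothed error statistics
# Returns fixed effects (as the internal m vector and as lth/beta), Omega
# and the error parameters. GLS and the Omega moment update are alternated
# to the joint complete-data MLE.
.mstep <- function(s_phi, s_S2, err, stack, spec, omega_prev) {
  n_sub <- stack$n_sub
  G <- length(stack$groups)
  cov_on <- spec$covariate == "group"
  p <- if (cov_on) G + 2L else 3L
  iv <- p - 1L; ik <- p  # positions of log-v, log-ka in m
  icl <- if (cov_on) stack$group_idx else rep.int(1L, n_sub)  # per subject
  # per-group sums of s_phi
  gsum <- rowsum(s_phi, stack$group_idx, reorder = TRUE)
  glev <- as.integer(rownames(gsum))
  ng <- tabulate(stack$group_idx, nbins = G)
  omega <- omega_prev
  m <- numeric(p)
  for (it in 1:50) {
    oi <- .pd_inv(omega)$inv
    A <- matrix(0, p, p); bvec <- numeric(p)
    for (gi in seq_along(glev)) {
      g <- glev[gi]
      ic <- if (cov_on) g else 1L
      idx <- c(ic, iv, ik)
      A[idx, idx] <- A[idx, idx] + ng[g] * oi
      bvec[idx] <- bvec[idx] + drop(oi %*% gsum[gi, ])
    }
    m_new <- solve(A, bvec)
    mu <- cbind(m_new[icl], m_new[iv], m_new[ik])
    O <- (s_S2 - crossprod(mu, s_phi) - crossprod(s_phi, mu) + crossprod(mu)) / n_sub
    O <- (O + t(O)) / 2
    if (spec$omega_structure == "diagonal") O <- diag(diag(O), 3L)
    done <- max(abs(m_new - m)) < 1e-12 && max(abs(O - omega)) < 1e-12
    m <- m_new; omega <- O
    if (done) break
  }
  a <- b <- 0
  if (spec$error_model == "additive") {
    a <- sqrt(err$ss_add / err$n)
  } else if (spec$error_model == "proportional") {
    b <- sqrt(err$ss_prop / err$n)
  } else {
    obj <- function(lp) {
      v <- exp(lp[1L]) + exp(lp[2L]) * err$f2
      sum(log(v) + err$r2 / v) / 2
    }
    st <- log(c(max(err$ss_add / err$n, 1e-6), max(err$ss_prop / err$n, 1e-6)))
    op <- stats::optim(st, obj, method = "BFGS",
                       control = list(maxit = 200, reltol = 1e-12))
    a <- sqrt(exp(op$par[1L])); b <- sqrt(exp(op$par[2L]))
  }
  ref <- 1L
  lth <- c(if (cov_on) m[ref] else m[1L], m[iv], m[ik])
  beta <- if (cov_on) m[seq_len(G)] - m[ref] else numeric(G)
  list(m = m, lth = lth, beta = beta, omega = omega, a = a, b = b,
       icl = icl, iv = iv, ik = ik, p = p, cov_on = cov_on)
}

#' Fit the population model by SAEM
#'
#' @param data A [pk_dataset()].
#' @param model_spec A [pk_model_spec()] describing the model structure.
#' @param cfg A [saem_config()].
#' @return An object of class `pk_fit` with elements `model` (the estimated
#'   [pk_model()]), `fixed_effects` (data frame of estimates, Louis-identity
#'   standard errors and 95% CIs), `loglik`/`loglik_mc_se`, `aic`/`bic`,
#'   `trajectories` (matrix, one row per iteration), `converged`,
#'   `acc_rates`, `eta` (last MCMC state), `se_method`, `seed`.
#' @export
fit_saem <- function(data, model_spec = pk_model_spec(), cfg = saem_config()) {
  stopifnot(inherits(data, "pk_dataset"), inherits(model_spec, "pk_model_spec"),
            inherits(cfg, "saem_config"))
  stack <- .stack_dataset(data, model_spec$blq)
  if (any(!is.finite(stack$y[!stack$cens])) || any(!is.finite(stack$t)))
    stop("dataset contains non-finite observations", call. = FALSE)
  if (sum(stack$n_obs_per_sub > 0) < 2L)
    stop("need at least 2 subjects with observations", call. = FALSE)
  if (length(unique(stack$t)) < 3L)
    stop("non-identifiable design: fewer than 3 distinct sampling times ",
         "pooled across subjects", call. = FALSE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  N <- stack$n_sub; G <- length(stack$groups); L <- cfg$n_chains
  K <- cfg$k1 + cfg$k2
  cov_on <- model_spec$covariate == "group"

  # initialisation: pooled NLS for theta, Omega = 0.3^2 I, beta = 0
  lth <- .nls_pooled_init(stack)
  beta <- numeric(G)
  omega <- diag(0.09, 3L)
  f0 <- {
    j <- stack$sub
    .css(rep(exp(lth[1L]), N)[j], exp(lth[2L]), exp(lth[3L]),
         stack$dose[j], stack$tau, stack$t)
  }
  r0 <- (stack$y - f0)[!stack$cens]
  a <- max(stats::sd(r0), 0.1); b <- max(stats::sd(r0 / pmax(f0[!stack$cens], 1)), 0.05)
  if (model_spec$error_model == "additive") b <- 0
  if (model_spec$error_model == "proportional") a <- 0

  eta <- replicate(L, matrix(0, N, 3L), simplify = FALSE)
  scales <- cfg$proposal_scale

  # smoothed sufficient statistics
  s_phi <- NULL; s_S2 <- NULL
  s_err <- list(ss_add = NULL, ss_prop = NULL, f2 = NULL, r2 = NULL,
                n = stack$n_obs)
  # Louis accumulators (filled during k2)
  p_fix <- if (cov_on) G + 2L else 3L
  s_D <- matrix(0, N, p_fix); s_DD <- matrix(0, p_fix, p_fix)
  louis_started <- FALSE

  traj_names <- c("cl_pop", "v_pop", "ka_pop",
                  if (cov_on && G > 1) paste0("beta_", stack$groups[-1L]),
                  "om_cl", "om_v", "om_ka", "err_a", "err_b")
  traj <- matrix(NA_real_, K, length(traj_names),
                 dimnames = list(NULL, traj_names))
  acc_tot <- numeric(3L); acc_n <- 0
  mstep_out <- NULL

  for (k in seq_len(K)) {
    gamma <- if (k <= cfg$k1) 1 else (k - cfg$k1)^(-cfg$step_exponent)
    pdo <- .pd_inv(omega, floor = 1e-10)
    o_inv <- pdo$inv; o_logdet <- pdo$logdet
    mu <- .mu_matrix(lth, beta, stack)

    acc_iter <- numeric(3L); prop_iter <- 0L
    phi_bar <- matrix(0, N, 3L); S2_bar <- matrix(0, 3L, 3L)
    fbar <- r2bar <- numeric(stack$n_obs)
    ss_add_bar <- ss_prop_bar <- 0
    D_bar <- matrix(0, N, p_fix); DD_bar <- matrix(0, p_fix, p_fix)

    for (ch in seq_len(L)) {
      e <- eta[[ch]]
      ll <- .loglik_rows(mu + e, stack, model_spec$error_model, a, b)
      ll[!.ka_ok(mu + e, model_spec$constrain_ka_gt_ke)] <- -Inf
      # kernel 1: independent proposal from the prior N(0, Omega);
      # acceptance ratio reduces to the likelihood ratio. This jump kernel
      # is what keeps the chain mixing across the correlated v/ka ridge.
      e_new <- .rmvnorm0(N, omega)
      ll_new <- .loglik_rows(mu + e_new, stack, model_spec$error_model, a, b)
      ll_new[!.ka_ok(mu + e_new, model_spec$constrain_ka_gt_ke)] <- -Inf
      accept <- log(stats::runif(N)) < (ll_new - ll)
      accept[!is.finite(ll_new)] <- FALSE
      e[accept, ] <- e_new[accept, , drop = FALSE]
      ll[accept] <- ll_new[accept]
      # kernel 2: component-wise Gaussian random walk sweeps
      pr <- .logprior_rows(e, o_inv, o_logdet)
      for (sw in seq_len(cfg$sweeps)) {
        for (cc in 1:3) {
          e_new <- e
          e_new[, cc] <- e[, cc] + scales[cc] * stats::rnorm(N)
          ll_new <- .loglik_rows(mu + e_new, stack, model_spec$error_model, a, b)
          ll_new[!.ka_ok(mu + e_new, model_spec$constrain_ka_gt_ke)] <- -Inf
          pr_new <- .logprior_rows(e_new, o_inv, o_logdet)
          accept <- log(stats::runif(N)) < (ll_new + pr_new - ll - pr)
          accept[!is.finite(ll_new)] <- FALSE
          e[accept, ] <- e_new[accept, , drop = FALSE]
          ll[accept] <- ll_new[accept]
          pr[accept] <- pr_new[accept]
          acc_iter[cc] <- acc_iter[cc] + mean(accept)
        }
        prop_iter <- prop_iter + 1L
      }
      eta[[ch]] <- e
      phi <- mu + e
      phi_bar <- phi_bar + phi / L
      S2_bar <- S2_bar + crossprod(phi) / L
      # error statistics at the current sample
      j <- stack$sub
      f <- .css(exp(phi[, 1L])[j], exp(phi[, 2L])[j], exp(phi[, 3L])[j],
                stack$dose[j], stack$tau, stack$t)
      r2 <- (stack$y - f)^2
      if (any(stack$cens)) {
        # M3: Gibbs-impute the latent censored values from the truncated
        # normal below the LLOQ so the closed-form M-step stays exact
        fc <- f[stack$cens]
        gc <- pmax(.resid_sd(model_spec$error_model, a, b, fc), 1e-10)
        lu <- log(stats::runif(length(fc))) +
          stats::pnorm(stack$lloq, fc, gc, log.p = TRUE)
        yc <- fc + gc * stats::qnorm(pmin(lu, -1e-12), log.p = TRUE)
        r2[stack$cens] <- (yc - fc)^2
      }
      fq <- pmax(f, 1e-6)
      ss_add_bar <- ss_add_bar + sum(r2) / L
      ss_prop_bar <- ss_prop_bar + sum(r2 / fq^2) / L
      fbar <- fbar + f / L; r2bar <- r2bar + r2 / L
      if (k > cfg$k1) {
        # Louis gradient of the complete-data loglik wrt the fixed effects:
        # D_i = X_i' Omega^-1 (phi_i - mu_i)
        R <- e %*% o_inv
        D <- matrix(0, N, p_fix)
        icl <- if (cov_on) stack$group_idx else rep.int(1L, N)
        D[cbind(seq_len(N), icl)] <- R[, 1L]
        D[, p_fix - 1L] <- D[, p_fix - 1L] + R[, 2L]
        D[, p_fix] <- D[, p_fix] + R[, 3L]
        D_bar <- D_bar + D / L
        DD_bar <- DD_bar + crossprod(D) / L
      }
    }
    acc_iter <- acc_iter / (cfg$sweeps * L)
    acc_tot <- acc_tot + acc_iter; acc_n <- acc_n + 1

    if (k <= cfg$k1) {  # adapt proposals during exploration only
      step <- min(0.5, 1 / sqrt(k))
      scales <- scales * exp(step * (acc_iter - cfg$accept_target))
      scales <- pmin(pmax(scales, 0.02), 5)
    }

    if (is.null(s_phi)) {
      s_phi <- phi_bar; s_S2 <- S2_bar
      s_err$ss_add <- ss_add_bar; s_err$ss_prop <- ss_prop_bar
      s_err$f2 <- fbar^2; s_err$r2 <- r2bar
    } else {
      s_phi <- s_phi + gamma * (phi_bar - s_phi)
      s_S2 <- s_S2 + gamma * (S2_bar - s_S2)
      s_err$ss_add <- s_err$ss_add + gamma * (ss_add_bar - s_err$ss_add)
      s_err$ss_prop <- s_err$ss_prop + gamma * (ss_prop_bar - s_err$ss_prop)
      s_err$f2 <- s_err$f2 + gamma * (fbar^2 - s_err$f2)
      s_err$r2 <- s_err$r2 + gamma * (r2bar - s_err$r2)
    }
    if (k > cfg$k1) {
      if (!louis_started) {
        s_D <- D_bar; s_DD <- DD_bar; louis_started <- TRUE
      } else {
        s_D <- s_D + gamma * (D_bar - s_D)
        s_DD <- s_DD + gamma * (DD_bar - s_DD)
      }
    }

    ms <- .mstep(s_phi, s_S2, s_err[c("ss_add", "ss_prop", "f2", "r2", "n")],
                 stack, model_spec, omega)
    if (k <= cfg$k1 && cfg$anneal > 0) {
      # keep variance components from collapsing during exploration
      d_old <- pmax(diag(ms$omega), 1e-12)
      dnew <- pmax(diag(ms$omega), cfg$anneal * diag(omega), 1e-12)
      sc <- pmin(sqrt(dnew / d_old), 1e6)
      ms$omega <- ms$omega * tcrossprod(sc)
      diag(ms$omega) <- dnew
      # the residual-error parameters are left free: flooring them props up
      # an inflated initial estimate and destabilises the proportional model
    }
    lth <- ms$lth; beta <- ms$beta; omega <- ms$omega; a <- ms$a; b <- ms$b
    mstep_out <- ms

    traj[k, ] <- c(exp(lth), if (cov_on && G > 1) beta[-1L],
                   sqrt(pmax(diag(omega), 0)), a, b)
  }

  # convergence flag: trailing relative movement of every trajectory
  w <- min(cfg$convergence_window, cfg$k2)
  tail_tr <- traj[(K - w + 1):K, , drop = FALSE]
  rel <- apply(tail_tr, 2, function(x) {
    s <- max(abs(mean(x)), 1e-6); (max(x) - min(x)) / s
  })
  converged <- all(rel < 0.1)

  # Louis observed information for the fixed effects
  se_method <- "louis"
  oi_fin <- .pd_inv(omega)$inv
  A <- matrix(0, p_fix, p_fix)
  ng <- tabulate(stack$group_idx, nbins = G)
  for (g in seq_len(G)) {
    if (ng[g] == 0) next
    ic <- if (cov_on) g else 1L
    idx <- c(ic, p_fix - 1L, p_fix)
    A[idx, idx] <- A[idx, idx] + ng[g] * oi_fin
  }
  info <- A - s_DD + crossprod(s_D)
  cov_m <- tryCatch(solve((info + t(info)) / 2), error = function(e) NULL)
  if (is.null(cov_m) || any(diag(cov_m) <= 0)) {
    se_method <- "failed"
    warning("Louis information matrix not positive definite; ",
            "standard errors unavailable", call. = FALSE)
    cov_m <- matrix(NA_real_, p_fix, p_fix)
  }

  # report table: theta on the natural scale (log-normal CIs), beta additive
  icl_ref <- 1L
  fe <- list()
  add_fe <- function(name, est, se_log, log_scale) {
    lo <- if (log_scale) est * exp(-1.96 * se_log) else est - 1.96 * se_log
    hi <- if (log_scale) est * exp(+1.96 * se_log) else est + 1.96 * se_log
    se_nat <- if (log_scale) est * se_log else se_log
    data.frame(parameter = name, estimate = est, se = se_nat,
               ci_lo = lo, ci_hi = hi)
  }
  fe[[1]] <- add_fe("cl_pop", exp(lth[1L]), sqrt(cov_m[icl_ref, icl_ref]), TRUE)
  fe[[2]] <- add_fe("v_pop", exp(lth[2L]), sqrt(cov_m[p_fix - 1L, p_fix - 1L]), TRUE)
  fe[[3]] <- add_fe("ka_pop", exp(lth[3L]), sqrt(cov_m[p_fix, p_fix]), TRUE)
  if (cov_on && G > 1) {
    for (g in 2:G) {
      vb <- cov_m[g, g] + cov_m[icl_ref, icl_ref] - 2 * cov_m[g, icl_ref]
      fe[[length(fe) + 1]] <- add_fe(paste0("beta_", stack$groups[g]),
                                     beta[g], sqrt(vb), FALSE)
    }
  }
  fixed_effects <- do.call(rbind, fe)
  rownames(fixed_effects) <- NULL

  model <- pk_model(theta = stats::setNames(exp(lth), c("cl", "v", "ka")),
                    groups = stack$groups,
                    beta = stats::setNames(beta, stack$groups)[-1L],
                    omega = omega, error_model = model_spec$error_model,
                    error_params = c(a = a, b = b))

  n_err <- if (model_spec$error_model == "combined") 2L else 1L
  n_om <- if (model_spec$omega_structure == "full") 6L else 3L
  npar <- p_fix + n_om + n_err

  fit <- structure(list(model = model, spec = model_spec, cfg = cfg,
                        fixed_effects = fixed_effects,
                        loglik = NA_real_, loglik_mc_se = NA_real_,
                        aic = NA_real_, bic = NA_real_, npar = npar,
                        trajectories = traj, converged = converged,
                        acc_rates = acc_tot / acc_n, proposal_scales = scales,
                        eta = eta[[1L]], seed = cfg$seed,
                        se_method = se_method,
                        n_subjects = N, n_obs = stack$n_obs,
                        n_blq_excluded = stack$n_blq_excluded),
                   class = "pk_fit")
  if (cfg$n_is > 0) {
    ll <- estimate_loglik_is(data, fit, n_is_samples = cfg$n_is,
                             seed = .child_seed(cfg$seed, 101L))
    fit$loglik <- ll$loglik; fit$loglik_mc_se <- ll$mc_se
    fit$aic <- -2 * ll$loglik + 2 * npar
    fit$bic <- -2 * ll$loglik + npar * log(stack$n_obs)
  }
  fit
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("SAEM population PK fit\n")
  cat(sprintf("  %d subjects, %d observations (%d BLQ excluded), %s error\n",
              x$n_subjects, x$n_obs, x$n_blq_excluded, x$spec$error_model))
  print(x$fixed_effects, row.names = FALSE, digits = 4)
  cat(sprintf("  omega SDs: %s\n",
              paste(sprintf("%.3f", sqrt(diag(x$model$omega))), collapse = " ")))
  cat(sprintf("  error: a = %.3g, b = %.3g | loglik = %.2f (MC se %.3f), AIC = %.1f, BIC = %.1f\n",
              x$model$error_params[["a"]], x$model$error_params[["b"]],
              x$loglik, x$loglik_mc_se, x$aic, x$bic))
  cat(sprintf("  converged: %s | MH acceptance: %s | SEs: %s\n",
              x$converged, paste(sprintf("%.2f", x$acc_rates), collapse = " "),
              x$se_method))
  invisible(x)
}
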