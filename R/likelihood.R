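# Marginal log-likelihood by per-subject importance sampling, model
# comparison across residual-error models, and the likelihood-ratio test.

# Subject view extracted from a stack.
.subject_view <- function(stack, i) {
  rows <- which(stack$sub == i)
  list(t = stack$t[rows], y = stack$y[rows], cens = stack$cens[rows],
       dose = stack$dose[i], gidx = stack$group_idx[i], n = length(rows))
}

# Support decomposition of Omega and the subject-level log-posterior in
# support coordinates z (eta = Q z, prior diagonal with variances lam).
.subject_target <- function(model, sv, tau, lloq) {
  ed <- eigen(model$omega, symmetric = TRUE)
  tol <- 1e-10 * max(abs(ed$values), 1)
  pos <- ed$values > tol
  r <- sum(pos)
  Q <- ed$vectors[, pos, drop = FALSE]
  lam <- ed$values[pos]
  g_lab <- model$groups[sv$gidx]
  mu <- c(log(model$theta[["cl"]]) + model$beta[[g_lab]],
          log(model$theta[["v"]]), log(model$theta[["ka"]]))
  a <- model$error_params[["a"]]; b <- model$error_params[["b"]]
  # vectorised over rows of Z (n x r); returns log posterior per row
  lp_rows <- function(Z) {
    n <- nrow(Z)
    eta <- Z %*% t(Q)
    # clamp to keep exp() and ratios finite; the prior dominates out there
    eta <- pmin(pmax(eta, -200), 200)
    cl <- exp(mu[1L] + eta[, 1L]); v <- exp(mu[2L] + eta[, 2L])
    ka <- exp(mu[3L] + eta[, 3L])
    ll <- numeric(n)
    if (sv$n > 0) {
      m <- sv$n
      f <- .css(rep(cl, each = m), rep(v, each = m), rep(ka, each = m),
                sv$dose, tau, rep(sv$t, times = n))
      g <- pmax(.resid_sd(model$error_model, a, b, f), 1e-10)
      li <- numeric(m * n)
      obs <- rep(!sv$cens, times = n)
      yy <- rep(sv$y, times = n)
      li[obs] <- stats::dnorm(yy[obs], f[obs], g[obs], log = TRUE)
      if (any(!obs))
        li[!obs] <- stats::pnorm(lloq, f[!obs], g[!obs], log.p = TRUE)
      ll <- .colSums(li, m, n)
    }
    prior <- -r / 2 * log(2 * pi) - sum(log(lam)) / 2 -
      colSums(t(Z^2) / lam) / 2
    out <- ll + prior
    # keep the optimiser on finite ground far from the mode
    out[!is.finite(out)] <- -1e10
    out
  }
  list(lp_rows = lp_rows, lp = function(z) lp_rows(matrix(z, 1L)),
       r = r, Q = Q, lam = lam, mu = mu)
}

.num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

.num_hess <- function(f, x, h = 1e-4) {
  r <- length(x)
  H <- matrix(0, r, r)
  f0 <- f(x)
  for (i in seq_len(r)) for (j in i:r) {
    xpp <- xpm <- xmp <- xmm <- x
    xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
    xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
    xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
    xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
    H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
  }
  H
}

# Maximise the subject posterior in support coordinates. Quasi-Newton from
# each start, then Newton polish on the numeric Hessian.
.cond_mode_z <- function(tg, starts, grad_tol = 1e-6) {
  neg <- function(z) -tg$lp(z)
  best <- NULL
  for (s in starts) {
    op <- tryCatch(stats::optim(s, neg, method = "BFGS",
                                control = list(maxit = 500, reltol = 1e-14)),
                   error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) stop("conditional-mode optimisation failed", call. = FALSE)
  z <- best$par
  for (nt in 1:25) {
    g <- .num_grad(neg, z)
    if (sqrt(sum(g^2)) < grad_tol / 10) break
    H <- .num_hess(neg, z)
    step <- tryCatch(solve(H, g), error = function(e) g)
    ok <- FALSE
    for (half in 0:10) {
      z_try <- z - step / 2^half
      if (neg(z_try) <= neg(z)) { z <- z_try; ok <- TRUE; break }
    }
    if (!ok) break
  }
  g <- .num_grad(neg, z)
  H <- .num_hess(neg, z)
  list(z = z, value = -neg(z), grad_norm = sqrt(sum(g^2)), hess = H)
}

#' Importance-sampling estimate of the marginal log-likelihood
#'
#' Per-subject importance sampling with a multivariate Student-t (4 df)
#' proposal centred at the subject's conditional mode with an inflated
#' curvature-based scale. With `Omega = 0` the marginal equals the
#' conditional likelihood at `eta = 0` and is returned exactly.
#'
#' @param data A [pk_dataset()].
#' @param fit A `pk_fit` or a [pk_model()].
#' @param n_is_samples Importance-sampling draws per subject.
#' @param seed Integer seed.
#' @return List with `loglik` (total) and `mc_se` (Monte-Carlo standard
#'   error, shrinking as `1/sqrt(n_is_samples)`).
#' @export
estimate_loglik_is <- function(data, fit, n_is_samples = 1000, seed = NULL) {
  model <- if (inherits(fit, "pk_fit")) fit$model else fit
  stopifnot(inherits(model, "pk_model"), inherits(data, "pk_dataset"))
  blq <- if (inherits(fit, "pk_fit")) fit$spec$blq else "exclude"
  if (!is.null(seed)) set.seed(seed)
  stack <- .stack_dataset(data, blq)
  total <- 0; var_tot <- 0
  nu <- 4
  for (i in seq_len(stack$n_sub)) {
    sv <- .subject_view(stack, i)
    tg <- .subject_target(model, sv, stack$tau, stack$lloq)
    if (tg$r == 0L || sv$n == 0L) {
      total <- total + tg$lp(numeric(tg$r))
      next
    }
    cm <- .cond_mode_z(tg, list(numeric(tg$r)))
    Sig <- tryCatch({
      S <- solve(cm$hess)
      if (any(!is.finite(S)) || any(diag(S) <= 0)) stop("bad")
      1.5 * (S + t(S)) / 2
    }, error = function(e) {
      warning("singular curvature for subject ", stack$ids[i],
              "; widened prior-based proposal used", call. = FALSE)
      2 * diag(tg$lam, tg$r)
    })
    Lc <- tryCatch(chol(Sig), error = function(e) chol(2 * diag(tg$lam, tg$r)))
    n <- n_is_samples
    Zn <- matrix(stats::rnorm(n * tg$r), n) %*% Lc
    wchi <- sqrt(stats::rchisq(n, nu) / nu)
    Z <- sweep(Zn, 1, wchi, "/")
    Z <- sweep(Z, 2, cm$z, "+")
    d2 <- rowSums(((Z - matrix(cm$z, n, tg$r, byrow = TRUE)) %*% solve(Lc))^2)
    logq <- lgamma((nu + tg$r) / 2) - lgamma(nu / 2) - tg$r / 2 * log(nu * pi) -
      sum(log(diag(Lc))) - (nu + tg$r) / 2 * log1p(d2 / nu)
    logw <- tg$lp_rows(Z) - logq
    mx <- max(logw)
    w <- exp(logw - mx)
    ll_i <- mx + log(mean(w))
    total <- total + ll_i
    var_tot <- var_tot + stats::var(w) / (n * mean(w)^2)
  }
  list(loglik = total, mc_se = sqrt(var_tot))
}

#' Compare residual-error models
#'
#' Fits the additive, proportional and combined residual-error models with
#' the same data, configuration and seed, and ranks them by BIC computed
#' from the importance-sampling marginal log-likelihood.
#'
#' @param data A [pk_dataset()].
#' @param skeleton A [pk_model_spec()] whose `error_model` field is replaced
#'   in turn.
#' @param cfg A [saem_config()]; its `n_is` must be > 0.
#' @return Data frame with one row per error model: `loglik`, `mc_se`,
#'   `npar`, `aic`, `bic`, `rank` (by BIC; failed fits ranked last) and
#'   `message` for failures.
#' @export
compare_error_models <- function(data, skeleton = pk_model_spec(),
                                 cfg = saem_config()) {
  stopifnot(cfg$n_is > 0)
  models <- c("additive", "proportional", "combined")
  rows <- vector("list", 3L)
  fits <- vector("list", 3L)
  for (i in seq_along(models)) {
    sk <- skeleton; sk$error_model <- models[i]
    res <- tryCatch({
      f <- fit_saem(data, sk, cfg)
      fits[[i]] <- f
      data.frame(error_model = models[i], loglik = f$loglik,
                 mc_se = f$loglik_mc_se, npar = f$npar, aic = f$aic,
                 bic = f$bic, message = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(error_model = models[i], loglik = NA_real_, mc_se = NA_real_,
                 npar = NA_integer_, aic = NA_real_, bic = NA_real_,
                 message = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  tab$rank <- rank(ifelse(is.na(tab$bic), Inf, tab$bic), ties.method = "first")
  attr(tab, "fits") <- fits
  tab
}

#' Likelihood-ratio test between nested fits
#'
#' @param fit_null,fit_alt `pk_fit` objects (or lists with a `loglik`
#'   element), the null nested in the alternative.
#' @param df Difference in the number of parameters.
#' @return List with `statistic` (`2 * (ll_alt - ll_null)`, clamped at 0
#'   with a warning when Monte-Carlo noise makes it negative) and `p` from
#'   the chi-square survival function.
#' @export
lrt <- function(fit_null, fit_alt, df) {
  ll0 <- fit_null$loglik; ll1 <- fit_alt$loglik
  if (is.na(ll0) || is.na(ll1))
    stop("log-likelihood estimates unavailable; fit with n_is > 0", call. = FALSE)
  stat <- 2 * (ll1 - ll0)
  if (stat < 0) {
    warning("negative LRT statistic clamped to 0 (Monte-Carlo noise)",
            call. = FALSE)
    stat <- 0
  }
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}
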