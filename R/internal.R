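# Internal stacked representation of a pk_dataset plus vectorised
# per-subject log-density kernels. Everything downstream (SAEM E-step,
# conditional modes, importance sampling) runs on this flat form so a
# proposal evaluation is a single pass over all observations.

# Build the stacked observation table. BLQ policy applied here once.
.stack_dataset <- function(data, blq = "exclude") {
  subs <- data$subjects
  n_sub <- length(subs)
  ids <- vapply(subs, `[[`, "", "id")
  grp <- vapply(subs, `[[`, "", "group")
  dose <- vapply(subs, `[[`, 0, "dose")
  group_idx <- match(grp, data$groups)
  t_all <- y_all <- numeric(0); cens_all <- logical(0); sub_all <- integer(0)
  n_blq_excluded <- 0L
  for (i in seq_len(n_sub)) {
    s <- subs[[i]]
    ti <- s$times; yi <- s$conc; ci <- s$blq
    if (blq == "exclude") {
      n_blq_excluded <- n_blq_excluded + sum(ci)
      keep <- !ci
      ti <- ti[keep]; yi <- yi[keep]; ci <- ci[keep]
    } else if (blq == "loq2") {
      yi[ci] <- data$lloq / 2
      ci[] <- FALSE
    }
    t_all <- c(t_all, ti); y_all <- c(y_all, yi)
    cens_all <- c(cens_all, ci); sub_all <- c(sub_all, rep.int(i, length(ti)))
  }
  # cumulative-sum trick for fast per-subject sums: observations are stored
  # grouped by subject, ends[i] = last row of subject i (ends[i-1] if none)
  ends <- integer(n_sub); last <- 0L
  for (i in seq_len(n_sub)) {
    last <- last + sum(sub_all == i)
    ends[i] <- last
  }
  list(n_sub = n_sub, n_obs = length(y_all), ids = ids, group_idx = group_idx,
       dose = dose, t = t_all, y = y_all, cens = cens_all, sub = sub_all,
       ends = ends, tau = data$tau, lloq = data$lloq, groups = data$groups,
       n_blq_excluded = n_blq_excluded,
       n_obs_per_sub = diff(c(0L, ends)))
}

.rowsum_sub <- function(x, stack) {
  diff(c(0, cumsum(x)[stack$ends]))
}

# Per-subject observation log-likelihood for an N x 3 matrix phi of
# individual log-parameters (log-cl, log-v, log-ka).
.loglik_rows <- function(phi, stack, error_model, a, b) {
  cl <- exp(phi[, 1L]); v <- exp(phi[, 2L]); ka <- exp(phi[, 3L])
  j <- stack$sub
  f <- .css(cl[j], v[j], ka[j], stack$dose[j], stack$tau, stack$t)
  g <- .resid_sd(error_model, a, b, f)
  ll <- numeric(stack$n_obs)
  obs <- !stack$cens
  ll[obs] <- stats::dnorm(stack$y[obs], f[obs], g[obs], log = TRUE)
  if (any(stack$cens))
    ll[stack$cens] <- stats::pnorm(stack$lloq, f[stack$cens], g[stack$cens],
                                   log.p = TRUE)
  .rowsum_sub(ll, stack)
}

# Per-subject MVN(0, omega) log prior for an N x 3 eta matrix, PD omega.
.logprior_rows <- function(eta, o_inv, o_logdet) {
  -3 / 2 * log(2 * pi) - o_logdet / 2 - rowSums((eta %*% o_inv) * eta) / 2
}

# mu matrix (N x 3) of population log-parameters per subject.
.mu_matrix <- function(lth, beta_by_group, stack) {
  cbind(lth[1L] + beta_by_group[stack$group_idx], lth[2L], lth[3L])
}

# ka > ke identifiability constraint, rowwise on phi.
.ka_ok <- function(phi, constrain) {
  if (!constrain) return(rep.int(TRUE, nrow(phi)))
  # log ka > log cl - log v
  phi[, 3L] > phi[, 1L] - phi[, 2L]
}

# Naive pooled nonlinear least squares on all observations (one set of
# structural parameters, per-subject doses honoured). Returns log-theta.
.nls_pooled_init <- function(stack) {
  y <- stack$y[!stack$cens]; t <- stack$t[!stack$cens]
  dose <- stack$dose[stack$sub][!stack$cens]
  if (!length(y)) stop("no quantifiable observations to initialise from",
                       call. = FALSE)
  # moment heuristic: AUC ~ mean conc * tau, V from a terminal-slope guess
  cl0 <- max(mean(dose) / (max(mean(y), 0.1) * stack$tau * 1000), 1e-4)
  start <- log(c(cl0, cl0 / 0.2, 1))
  obj <- function(lp) {
    cl <- exp(lp[1L]); v <- exp(lp[2L]); ka <- exp(lp[3L])
    if (ka <= cl / v) return(1e10)
    f <- .css(rep(cl, length(t)), v, ka, dose, stack$tau, t)
    sum((y - f)^2)
  }
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit2 <- stats::optim(fit$par, obj, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
  if (fit2$value <= fit$value) fit2$par else fit$par
}

# Draw N samples from MVN(0, omega) via eigendecomposition (PSD-safe).
.rmvnorm0 <- function(n, omega) {
  ed <- eigen(as.matrix(omega), symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  z <- matrix(stats::rnorm(n * length(lam)), n)
  z %*% (t(ed$vectors) * sqrt(lam))
}

# Derive a deterministic child seed below 2^31 from a user seed.
.child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
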