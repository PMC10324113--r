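# Downstream inference on the PK outputs: group exposure contrasts,
# variance-equality tests, eta-covariate association, correlations and the
# 2^-ddCt qPCR quantification. Every test returns a uniform record (name,
# statistic, df, p, group sizes) so reports can serialise them directly.

.test_record <- function(test, statistic, df, p, n = NULL, extra = list()) {
  structure(c(list(test = test, statistic = statistic, df = df, p = p, n = n),
              extra),
            class = "pk_test")
}

#' @export
print.pk_test <- function(x, ...) {
  dfs <- paste(x$df, collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$test, x$statistic, dfs, x$p))
  invisible(x)
}

#' Signed percent change between two means
#'
#' @param ref_mean Reference mean (> 0).
#' @param new_mean New mean.
#' @return `100 * (new_mean - ref_mean) / ref_mean`.
#' @examples
#' percent_change(195.4, 131.1)  # -32.9, i.e. a 33% reduction
#' @export
percent_change <- function(ref_mean, new_mean) {
  if (!is.numeric(ref_mean) || ref_mean <= 0)
    stop("'ref_mean' must be > 0", call. = FALSE)
  100 * (new_mean - ref_mean) / ref_mean
}

#' Two-sample variance-ratio (F) test
#'
#' Tests equality of variances of two samples via `F = s_x^2 / s_y^2` with
#' a two-sided p-value from the F distribution on `(n_x - 1, n_y - 1)`
#' degrees of freedom. This is the standard two-group equality-of-variance
#' companion to the Brown-Forsythe test for more than two groups.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return A `pk_test` record with `statistic` (F), `df`, `p`.
#' @export
variance_ratio_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each sample needs n >= 2", call. = FALSE)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0)
    stop("both samples have zero variance; F undefined", call. = FALSE)
  if (vx == 0 || vy == 0) {
    warning("one sample has zero variance; p = 0 by convention", call. = FALSE)
    return(.test_record("variance_ratio_F", if (vy == 0) Inf else 0,
                        c(length(x) - 1L, length(y) - 1L), 0,
                        n = c(length(x), length(y))))
  }
  f <- vx / vy
  df1 <- length(x) - 1L; df2 <- length(y) - 1L
  p <- 2 * min(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
  p <- min(p, 1)
  .test_record("variance_ratio_F", f, c(df1, df2), p, n = c(length(x), length(y)))
}

#' One-way ANOVA
#'
#' Standard between/within variance decomposition.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (>= 2 groups, total
#'   n > number of groups).
#' @return A `pk_test` record with `statistic` (F), `df = c(k-1, n-k)`, `p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  k <- nlevels(groups); n <- length(values)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (n <= k) stop("need total n > number of groups", call. = FALSE)
  gm <- tapply(values, groups, mean)
  ng <- tabulate(groups)
  grand <- mean(values)
  ssb <- sum(ng * (gm - grand)^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  df1 <- k - 1L; df2 <- n - k
  if (ssw == 0) {
    p <- if (ssb > 0) 0 else 1
    f <- if (ssb > 0) Inf else 0
    return(.test_record("anova_oneway", f, c(df1, df2), p, n = as.integer(ng)))
  }
  f <- (ssb / df1) / (ssw / df2)
  .test_record("anova_oneway", f, c(df1, df2),
               stats::pf(f, df1, df2, lower.tail = FALSE), n = as.integer(ng))
}

#' Brown-Forsythe test of equality of variances
#'
#' One-way ANOVA on the absolute deviations from the group medians.
#'
#' @param groups A list of numeric samples (each n >= 2), or a numeric
#'   vector with `g` a grouping vector.
#' @param g Optional grouping vector when `groups` is a numeric vector.
#' @return A `pk_test` record.
#' @export
brown_forsythe <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  dev <- lapply(groups, function(x) abs(x - stats::median(x)))
  values <- unlist(dev, use.names = FALSE)
  lab <- rep(seq_along(dev), vapply(dev, length, 0L))
  out <- anova_oneway(values, lab)
  out$test <- "brown_forsythe"
  out
}

#' Association of random effects with the treatment group
#'
#' One-way ANOVA of each eta component (from a no-covariate fit) across
#' treatment groups; the standard mechanism for detecting a covariate
#' effect on a PK parameter. Reports unadjusted and Bonferroni-adjusted
#' p-values (3 simultaneous components).
#'
#' @param eta_matrix Numeric matrix (subjects x 3) or data frame with
#'   columns `eta_cl`, `eta_v`, `eta_ka`.
#' @param groups Treatment-group labels per subject.
#' @return Data frame with one row per eta component: `F`, `df1`, `df2`,
#'   `p`, `p_bonferroni`.
#' @export
eta_covariate_test <- function(eta_matrix, groups) {
  em <- if (is.data.frame(eta_matrix))
    as.matrix(eta_matrix[, c("eta_cl", "eta_v", "eta_ka")])
  else as.matrix(eta_matrix)
  stopifnot(ncol(em) == 3L, nrow(em) == length(groups))
  rows <- lapply(1:3, function(k) {
    if (stats::var(em[, k]) == 0) {
      # identical etas carry no group signal
      return(data.frame(parameter = c("eta_cl", "eta_v", "eta_ka")[k],
                        F = 0, df1 = NA_integer_, df2 = NA_integer_, p = 1))
    }
    tst <- anova_oneway(em[, k], groups)
    data.frame(parameter = c("eta_cl", "eta_v", "eta_ka")[k],
               F = tst$statistic, df1 = tst$df[1L], df2 = tst$df[2L], p = tst$p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * 3, 1)
  out
}

#' Pearson correlation test
#'
#' Product-moment correlation with a two-sided p-value from
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, `n >= 3`, finite, non-constant.
#' @return A `pk_test` record with `statistic` = r (and `t`, `n` extras).
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need n >= 3 paired values", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0; tval <- sign(r) * Inf
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  .test_record("pearson", r, n - 2L, p, n = n, extra = list(t = tval))
}

# ranks with average ties
.rank_avg <- function(x) rank(x, ties.method = "average")

# all permutations of 1..n (n small)
.perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L))
  sub <- .perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation test
#'
#' Pearson correlation of the (average-tie) ranks. The two-sided p-value is
#' exact by full permutation enumeration for `n <= 9` (no ties), otherwise
#' via the t approximation.
#'
#' @inheritParams pearson_test
#' @return A `pk_test` record with `statistic` = rho.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need n >= 3 paired values", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  rx <- .rank_avg(x); ry <- .rank_avg(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 9L && !ties) {
    pm <- .perms(n)
    # rho for every permutation of y's ranks against fixed rx
    rhos <- apply(pm, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) p <- 0
    else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
    }
    method <- "t-approx"
  }
  .test_record("spearman", rho, n - 2L, p, n = n, extra = list(method = method))
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target_t,ct_ref_t Ct of target and reference gene, treated.
#' @param ct_target_c,ct_ref_c Ct of target and reference gene, control.
#' @return Fold change `2^-((ct_target_t - ct_ref_t) - (ct_target_c - ct_ref_c))`.
#' @examples
#' ddct_fold_change(24, 20, 25, 20)  # 2
#' @export
ddct_fold_change <- function(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c) {
  args <- c(ct_target_t, ct_ref_t, ct_target_c, ct_ref_c)
  if (any(!is.finite(args))) stop("Ct values must be finite", call. = FALSE)
  2^-((ct_target_t - ct_ref_t) - (ct_target_c - ct_ref_c))
}

#' Per-group summary of individual AUCs
#'
#' @param estimates Data frame with columns `group` and `auc` (e.g. from
#'   [ebe_estimates()]).
#' @param groups Optional ordering of group labels; defaults to order of
#'   appearance.
#' @return Data frame per group: `n`, `mean`, `variance` (unbiased; `NA`
#'   for n = 1), t-based 95% CI bounds.
#' @export
group_auc_summary <- function(estimates, groups = NULL) {
  stopifnot(all(c("group", "auc") %in% names(estimates)))
  if (is.null(groups)) groups <- unique(estimates$group)
  rows <- lapply(groups, function(g) {
    x <- estimates$auc[estimates$group == g]
    if (!length(x)) stop("no estimates for group ", g, call. = FALSE)
    n <- length(x); m <- mean(x)
    v <- if (n > 1) stats::var(x) else NA_real_
    half <- if (n > 1) stats::qt(0.975, n - 1) * sqrt(v / n) else NA_real_
    data.frame(group = g, n = n, mean = m, variance = v,
               ci_lo = m - half, ci_hi = m + half, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
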