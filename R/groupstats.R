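#' Wilcoxon-Mann-Whitney rank test
#'
#' Two-sided comparison of two independent samples.  The exact null
#' distribution is used when the combined sample size is at most 20 and
#' there are no ties; otherwise the normal approximation with tie
#' correction (no continuity correction) is used.
#'
#' @param x,y numeric samples (each non-empty; `NA` dropped).
#' @return list with `statistic` (Mann-Whitney U for `x`) and `p_value`.
#' @export
wilcoxon_mw <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact)
}

# conditional probabilities of 2xC tables given all margins (psi = 1):
# enumerate first-row count vectors; probability proportional to
# prod(choose(col_margin_j, x_j)).
enumerate_2xc <- function(col_margins, r1) {
  ranges <- lapply(col_margins, function(cm) 0:cm)
  grid <- as.matrix(expand.grid(ranges))
  grid[rowSums(grid) == r1, , drop = FALSE]
}

#' Minimum-likelihood two-sided exact test for a 2 x C table
#'
#' Enumerates every table with the observed margins; the two-sided P-value
#' is the total conditional probability of tables whose probability does not
#' exceed that of the observed table (relative slack 1e-7 against floating-
#' point ties).  For 2 x 2 tables this is the classic two-sided Fisher
#' exact test; larger C uses the multivariate hypergeometric.
#'
#' @param table integer matrix with 2 rows; non-negative counts, all margins
#'   positive.
#' @return an `exact_table_result` list: `p_value`, `table`.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2) stop("table must have 2 rows")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero margin")
  r1 <- sum(tab[1, ])
  cm <- colSums(tab)
  states <- enumerate_2xc(cm, r1)
  logp <- rowSums(vapply(seq_along(cm), function(j) {
    lchoose(cm[j], states[, j])
  }, numeric(nrow(states))))
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  obs <- which(apply(states, 1, function(s) all(s == tab[1, ])))
  p <- sum(prob[prob <= prob[obs] * (1 + 1e-7)])
  structure(list(p_value = min(p, 1), table = tab, method = "minimum likelihood"),
            class = "exact_table_result")
}

# conditional (noncentral hypergeometric) distribution of the [1,1] cell
cond_dist <- function(m1, m2, n1, log_psi) {
  lo <- max(0, n1 - m2)
  hi <- min(n1, m1)
  x <- lo:hi
  lf <- lchoose(m1, x) + lchoose(m2, n1 - x) + x * log_psi
  f <- exp(lf - max(lf))
  list(x = x, f = f / sum(f))
}

minlik_p_psi <- function(a, m1, m2, n1, log_psi) {
  d <- cond_dist(m1, m2, n1, log_psi)
  fobs <- d$f[d$x == a]
  sum(d$f[d$f <= fobs * (1 + 1e-7)])
}

#' Conditional-MLE odds ratio with exact confidence interval
#'
#' The odds ratio is estimated by conditional maximum likelihood under
#' Fisher's noncentral hypergeometric distribution (the value of psi at
#' which the expected [1,1] cell equals the observed one), and the
#' confidence interval is obtained by inverting the two-sided
#' minimum-likelihood exact test: the interval contains the psi values whose
#' exact P exceeds `1 - level`.
#'
#' @param table 2 x 2 count matrix with positive margins.
#' @param level confidence level (default 0.95).
#' @return an `exact_table_result` list: `or` (cMLE), `ci`, `p_value`
#'   (min-lik two-sided P at psi = 1), `level`.
#' @export
odds_ratio_cmle <- function(table, level = 0.95) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2 x 2")
  a <- tab[1, 1]
  m1 <- sum(tab[1, ])
  m2 <- sum(tab[2, ])
  n1 <- sum(tab[, 1])
  if (m1 == 0 || m2 == 0 || n1 == 0 || sum(tab[, 2]) == 0) stop("zero margin")
  lo_sup <- max(0, n1 - m2)
  hi_sup <- min(n1, m1)
  or <- if (a == lo_sup) 0 else if (a == hi_sup) Inf else {
    exp(stats::uniroot(function(lp) {
      d <- cond_dist(m1, m2, n1, lp)
      sum(d$x * d$f) - a
    }, c(-25, 25), tol = 1e-10)$root)
  }
  alpha <- 1 - level
  pfun <- function(lp) minlik_p_psi(a, m1, m2, n1, lp)
  # invert the min-lik test by scanning outward from the estimate on a log
  # grid and refining each crossing by bisection
  grid <- seq(-25, 25, length.out = 3001)
  pv <- vapply(grid, pfun, numeric(1))
  inside <- which(pv > alpha)
  if (!length(inside)) {
    ci <- c(NA_real_, NA_real_)
  } else {
    lo_i <- min(inside)
    hi_i <- max(inside)
    refine <- function(l_out, l_in) {
      if (l_out == l_in) return(grid[l_in])
      f <- function(lp) pfun(lp) - alpha
      stats::uniroot(f, sort(c(grid[l_out], grid[l_in])), tol = 1e-8)$root
    }
    ci_lo <- if (lo_i == 1) 0 else exp(refine(lo_i - 1, lo_i))
    ci_hi <- if (hi_i == length(grid)) Inf else exp(refine(hi_i + 1, hi_i))
    ci <- c(ci_lo, ci_hi)
  }
  structure(list(or = or, ci = ci, level = level,
                 p_value = pfun(0), table = tab),
            class = "exact_table_result")
}

#' @export
print.exact_table_result <- function(x, ...) {
  if (!is.null(x$or)) {
    cat(sprintf("cMLE odds ratio %.3f, %d%% CI (%.3f, %.3f), exact P = %.4g\n",
                x$or, round(x$level * 100), x$ci[1], x$ci[2], x$p_value))
  } else {
    cat(sprintf("Minimum-likelihood exact test: P = %.4g\n", x$p_value))
  }
  invisible(x)
}

# ---- multivariate / univariate linear-model machinery --------------------

# Build design matrices for a group comparison with optional covariates.
# Returns listwise-complete data and thin-Q factors for the reduced
# (covariates-only) and full (covariates + group) models.
lm_designs <- function(Y, group, covariates = NULL) {
  Y <- as.matrix(Y)
  group <- factor(group)
  keep <- stats::complete.cases(Y, group)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    keep <- keep & stats::complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  Y <- Y[keep, , drop = FALSE]
  group <- droplevels(group[keep])
  n <- nrow(Y)
  X_red <- cbind(`(Intercept)` = rep(1, n), covariates)
  G <- stats::model.matrix(~group)[, -1, drop = FALSE]
  X_full <- cbind(X_red, G)
  if (qr(X_full)$rank < ncol(X_full)) stop("singular design")
  list(Y = Y, group = group, n = n,
       q = ncol(Y), df_h = nlevels(group) - 1,
       df_e = n - ncol(X_full),
       Q_red = qr.Q(qr(X_red)), Q_full = qr.Q(qr(X_full)))
}

# error and hypothesis cross-product matrices for a response matrix
hyp_err <- function(d, Y) {
  cf <- crossprod(d$Q_full, Y)
  cr <- crossprod(d$Q_red, Y)
  E <- crossprod(Y) - crossprod(cf)
  H <- crossprod(cf) - crossprod(cr)
  list(H = H, E = E)
}

pillai_trace <- function(H, E) {
  sum(diag(H %*% solve(H + E)))
}

#' Pillai-trace MANOVA / MANCOVA for a group effect
#'
#' Tests the diagnostic-group term on a multivariate response, adjusted for
#' optional covariates: `V = trace(H (H + E)^{-1})` where H and E are the
#' hypothesis and error cross-product matrices of the group term after the
#' covariates.  The standard F approximation provides the parametric P.
#' With a single response, V equals the (partial) eta-squared of the group
#' term.
#'
#' @param Y n x q response matrix (listwise-complete rows are used).
#' @param group factor-like group labels.
#' @param covariates optional numeric covariate matrix.
#' @return a `perm_test_result` list: `statistic = "pillai_V"`, `value`,
#'   `F`, `df`, `p_parametric`.
#' @export
pillai_manova <- function(Y, group, covariates = NULL) {
  d <- lm_designs(Y, group, covariates)
  if (d$n <= d$q + ncol(d$Q_full)) stop("too few rows for the model")
  he <- hyp_err(d, d$Y)
  V <- pillai_trace(he$H, he$E)
  s <- min(d$q, d$df_h)
  m <- (abs(d$df_h - d$q) - 1) / 2
  nn <- (d$df_e - d$q + d$df_h - max(d$q, d$df_h)) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fstat <- (df2 / df1) * V / (s - V)
  structure(list(statistic = "pillai_V", value = V, F = Fstat,
                 df = c(df1, df2),
                 p_parametric = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 n = d$n),
            class = "perm_test_result")
}

#' Freedman-Lane permutation P-value for a group effect
#'
#' Permutation inference that respects covariates: the reduced
#' (covariates-only) model is fitted once, and each permutation adds
#' permuted reduced-model residuals back onto the reduced fitted values
#' before recomputing the group statistic from the full model.  With no
#' covariates this reduces to permuting the raw responses.  The empirical P
#' uses the add-one convention `(1 + #{stat* >= stat_obs}) / (1 + n_perm)`
#' and therefore can never be zero.
#'
#' @param Y response matrix (multivariate) or vector.
#' @param group group labels.
#' @param covariates optional covariate matrix.
#' @param statistic `"pillai"` (Pillai trace V) or `"F"` (univariate F).
#' @param n_perm number of permutations (default 2000; the full-scale
#'   analysis uses 50000).
#' @param seed integer seed.
#' @return a `perm_test_result` list with `value`, `p_parametric`,
#'   `p_perm`, `n_perm`.
#' @export
freedman_lane_p <- function(Y, group, covariates = NULL,
                            statistic = c("pillai", "F"),
                            n_perm = 2000, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_perm < 1) stop("n_perm must be >= 1")
  d <- lm_designs(Y, group, covariates)
  if (!is.null(seed)) set.seed(seed)
  stat_fn <- if (statistic == "pillai") {
    function(Y) {
      he <- hyp_err(d, Y)
      pillai_trace(he$H, he$E)
    }
  } else {
    if (d$q != 1) stop("statistic 'F' requires a single response")
    function(Y) {
      he <- hyp_err(d, Y)
      (he$H[1, 1] / d$df_h) / (he$E[1, 1] / d$df_e)
    }
  }
  fitted_red <- d$Q_red %*% crossprod(d$Q_red, d$Y)
  resid_red <- d$Y - fitted_red
  obs <- stat_fn(d$Y)
  count <- 0L
  for (b in seq_len(n_perm)) {
    Yb <- fitted_red + resid_red[sample.int(d$n), , drop = FALSE]
    if (stat_fn(Yb) >= obs) count <- count + 1L
  }
  par <- if (statistic == "pillai") pillai_manova(d$Y, d$group,
    if (ncol(d$Q_red) > 1) d$Q_red[, -1, drop = FALSE])
  structure(list(statistic = statistic, value = obs,
                 p_parametric = if (!is.null(par)) par$p_parametric,
                 p_perm = (1 + count) / (1 + n_perm),
                 n_perm = n_perm, n = d$n),
            class = "perm_test_result")
}

#' Univariate follow-up ANOVA / ANCOVA with permutation P
#'
#' F test for the group term (adjusted for covariates when given) with
#' effect sizes: eta-squared `SS_group / SS_total` for the unadjusted model
#' and partial eta-squared `SS_group / (SS_group + SS_error)` (the two
#' coincide with no covariates).  The empirical P comes from the
#' Freedman-Lane procedure.
#'
#' @param y numeric response.
#' @param group group labels.
#' @param covariates optional covariate matrix.
#' @param n_perm Freedman-Lane permutations (0 skips the permutation P).
#' @param seed integer seed.
#' @return a `perm_test_result` list: `value` (F), `df`, `p_parametric`,
#'   `eta2`, `etap2`, `p_perm`.
#' @export
univariate_followup <- function(y, group, covariates = NULL, n_perm = 2000,
                                seed = NULL) {
  d <- lm_designs(matrix(y, ncol = 1), group, covariates)
  he <- hyp_err(d, d$Y)
  ss_h <- he$H[1, 1]
  ss_e <- he$E[1, 1]
  ss_tot <- sum((d$Y - mean(d$Y))^2)
  Fstat <- (ss_h / d$df_h) / (ss_e / d$df_e)
  p_perm <- NA_real_
  if (n_perm > 0) {
    fl <- freedman_lane_p(d$Y, d$group,
                          covariates = if (ncol(d$Q_red) > 1) d$Q_red[, -1, drop = FALSE],
                          statistic = "F", n_perm = n_perm, seed = seed)
    p_perm <- fl$p_perm
  }
  structure(list(statistic = "F", value = Fstat,
                 df = c(d$df_h, d$df_e),
                 p_parametric = stats::pf(Fstat, d$df_h, d$df_e, lower.tail = FALSE),
                 eta2 = ss_h / ss_tot,
                 etap2 = ss_h / (ss_h + ss_e),
                 p_perm = p_perm, n_perm = n_perm, n = d$n),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("%s = %.4f", x$statistic, x$value))
  if (!is.null(x$df)) cat(sprintf(", df = (%g, %g)", x$df[1], x$df[2]))
  if (!is.null(x$p_parametric) && length(x$p_parametric)) {
    cat(sprintf(", P = %.4g", x$p_parametric))
  }
  if (!is.null(x$p_perm) && !is.na(x$p_perm)) {
    cat(sprintf(", P_perm/boot = %.4g (B = %d)", x$p_perm, x$n_perm))
  }
  if (!is.null(x$eta2)) cat(sprintf(", eta2 = %.3f", x$eta2))
  cat("\n")
  invisible(x)
}
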