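# Spearman rho with t-approximation P for one pair of vectors (pairwise
# complete).  Returns NA rho (flagged) for constant input.
spearman_one <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  n <- sum(keep)
  if (n < 3) return(list(rho = NA_real_, n = n, p = NA_real_))
  xr <- rank(x[keep])
  yr <- rank(y[keep])
  if (stats::sd(xr) == 0 || stats::sd(yr) == 0) {
    return(list(rho = NA_real_, n = n, p = NA_real_))
  }
  rho <- stats::cor(xr, yr)
  if (n < 4) return(list(rho = rho, n = n, p = NA_real_))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  list(rho = rho, n = n, p = p)
}

#' Spearman correlation screen between two variable blocks
#'
#' Rank correlations (average ranks for ties) between every X-block /
#' Y-block variable pair, each computed over all pairwise non-missing
#' observations, with P-values from the t approximation.  Constant variables
#' yield a flagged `NA` rather than an error.
#'
#' @param X_block,Y_block data.frames (or matrices) of numeric variables.
#'   When `Y_block` is omitted the screen is `X_block` against itself.
#' @return long-format data.frame (class `corr_result`): `x`, `y`, `rho`,
#'   `n`, `p`.
#' @export
spearman_matrix <- function(X_block, Y_block = NULL) {
  X <- as.data.frame(X_block)
  Y <- if (is.null(Y_block)) X else as.data.frame(Y_block)
  out <- expand.grid(x = names(X), y = names(Y), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(xn, yn) {
    unlist(spearman_one(X[[xn]], Y[[yn]]))
  }, out$x, out$y)
  out$rho <- res["rho", ]
  out$n <- as.integer(res["n", ])
  out$p <- res["p", ]
  class(out) <- c("corr_result", "data.frame")
  out
}

#' Storey q-values with bootstrap pi0 estimation
#'
#' Converts a family of P-values into q-values (the minimum false discovery
#' rate at which each test is called significant).  The proportion of true
#' nulls pi0 is estimated over the lambda grid 0.05..0.95 (step 0.05) by the
#' bootstrap method: the lambda minimizing the bootstrap mean squared error
#' of `pi0(lambda)` around the minimum plug-in estimate is selected.
#' Q-values are `pi0 * m * p / rank`, monotonized from the largest P down.
#'
#' @param p_list numeric vector of P-values in `[0, 1]` (NA allowed,
#'   passed through).
#' @param n_boot bootstrap draws for the MSE estimate (default 100).
#' @param pi0 optionally force pi0 (e.g. 1 gives Benjamini-Hochberg).
#' @param seed integer seed for the bootstrap.
#' @return list with `q` (same length/order as `p_list`), `pi0`,
#'   `fdr_at_05` (estimated FDR incurred when every P < 0.05 is called
#'   significant), `n_sig_q05` (tests with q < 0.05).
#' @export
qvalues <- function(p_list, n_boot = 100, pi0 = NULL, seed = NULL) {
  p_all <- p_list
  ok <- !is.na(p_all)
  p <- p_all[ok]
  if (!length(p)) stop("empty P-value list")
  if (any(p < 0 | p > 1)) stop("P-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    lambdas <- seq(0.05, 0.95, by = 0.05)
    pi0_hat <- vapply(lambdas, function(l) mean(p > l) / (1 - l), numeric(1))
    # target: lower decile of the plug-in curve (stabler than the minimum)
    min_pi0 <- stats::quantile(pi0_hat, 0.1, names = FALSE)
    if (!is.null(seed)) set.seed(seed)
    mse <- rep(0, length(lambdas))
    for (b in seq_len(n_boot)) {
      pb <- p[sample.int(m, m, replace = TRUE)]
      pi0_b <- vapply(lambdas, function(l) mean(pb > l) / (1 - l), numeric(1))
      mse <- mse + (pi0_b - min_pi0)^2
    }
    pi0 <- pi0_hat[which.min(mse)]
    pi0 <- min(max(pi0, 0), 1)
    if (pi0 == 0) pi0 <- 1 / m   # degenerate family: keep q well-defined
  }
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  prev <- 1
  ranks <- rank(p, ties.method = "max")
  for (i in ord) {
    prev <- min(prev, pi0 * p[i] * m / ranks[i])
    q[i] <- prev
  }
  out <- rep(NA_real_, length(p_all))
  out[ok] <- q
  n05 <- sum(p < 0.05)
  list(q = out, pi0 = pi0,
       fdr_at_05 = if (n05 > 0) min(1, pi0 * 0.05 * m / n05) else NA_real_,
       n_sig_q05 = sum(q < 0.05))
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables, residualizes x and y on the controls by
#' least squares, and correlates the residuals; P from the t distribution
#' with `n - 2 - k` degrees of freedom.  Complete cases only.
#'
#' @param x,y numeric vectors.
#' @param controls data.frame/matrix of control variables.
#' @return `corr_result`-style one-row data.frame with `rho`, `n`, `p` and
#'   the control names.
#' @export
partial_spearman <- function(x, y, controls) {
  Z <- as.matrix(controls)
  keep <- !is.na(x) & !is.na(y) & stats::complete.cases(Z)
  k <- ncol(Z)
  n <- sum(keep)
  if (n < k + 4) stop("too few complete cases for the partial correlation")
  xr <- rank(x[keep])
  yr <- rank(y[keep])
  Zr <- apply(Z[keep, , drop = FALSE], 2, rank)
  X <- cbind(1, Zr)
  if (qr(X)$rank < ncol(X)) stop("singular control design")
  rx <- stats::lm.fit(X, xr)$residuals
  ry <- stats::lm.fit(X, yr)$residuals
  # a variable fully explained by the controls has no residual variation
  # left to correlate: define the partial correlation as zero
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    out <- data.frame(x = "x", y = "y", rho = 0, n = n, p = 1,
                      controls = paste(colnames(Z) %||% paste0("z", seq_len(k)),
                                       collapse = ","),
                      stringsAsFactors = FALSE)
    class(out) <- c("corr_result", "data.frame")
    return(out)
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- rho * sqrt(df / (1 - rho^2))
  p <- if (abs(rho) >= 1 - 1e-15) 0 else 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  out <- data.frame(x = "x", y = "y", rho = rho, n = n, p = p,
                    controls = paste(colnames(Z) %||% paste0("z", seq_len(k)),
                                     collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("corr_result", "data.frame")
  out
}
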