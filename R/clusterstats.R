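# Vectorized one-way F statistics for a n x B matrix of responses.
oneway_F_cols <- function(Ystar, rows_by_group, n, k) {
  sst <- colSums(Ystar^2) - colSums(Ystar)^2 / n
  ssb <- -colSums(Ystar)^2 / n
  for (rows in rows_by_group) {
    ssb <- ssb + colSums(Ystar[rows, , drop = FALSE])^2 / length(rows)
  }
  ssw <- sst - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Cluster-stratified bootstrap one-way ANOVA
#'
#' The observed one-way F for differences across clusters is compared with a
#' null distribution generated by nonparametric bootstrap resampling of the
#' response with between-cluster mean differences nullified: each cluster's
#' values are centered on the grand mean (preserving within-cluster
#' distributions exactly) and resampled with replacement within cluster,
#' keeping cluster sizes fixed.  `P_boot = (1 + #{F* >= F}) / (1 + B)`.
#'
#' @param y numeric response (`NA` rows dropped).
#' @param cluster_labels cluster assignment (each cluster needs >= 2
#'   members).
#' @param B bootstrap draws (default 2000; full-scale analyses use 50000).
#' @param seed integer seed.
#' @return a `perm_test_result` with `value` (F), `df`, `p_parametric`,
#'   `p_perm` (the bootstrap P), `eta2`.
#' @export
boot_oneway_anova <- function(y, cluster_labels, B = 2000, seed = NULL) {
  keep <- !is.na(y) & !is.na(cluster_labels)
  y <- y[keep]
  g <- factor(cluster_labels[keep])
  k <- nlevels(g)
  n <- length(y)
  if (k < 2) stop("need at least 2 clusters")
  sizes <- table(g)
  if (any(sizes < 2)) stop("cluster of size 1: within-cluster resampling undefined")
  if (!is.null(seed)) set.seed(seed)
  rows_by_group <- split(seq_len(n), g)
  F_obs <- oneway_F_cols(matrix(y, ncol = 1), rows_by_group, n, k)
  means <- tapply(y, g, mean)
  y0 <- y - means[g] + mean(y)   # nullified response
  count <- 0L
  chunk <- 10000L
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    Ystar <- matrix(NA_real_, n, nb)
    for (gi in seq_len(k)) {
      rows <- rows_by_group[[gi]]
      vals <- y0[rows]
      Ystar[rows, ] <- vals[sample.int(length(rows), length(rows) * nb,
                                       replace = TRUE)]
    }
    F_b <- oneway_F_cols(Ystar, rows_by_group, n, k)
    F_b[is.nan(F_b)] <- 0   # degenerate draw: zero between and within SS
    count <- count + sum(F_b >= F_obs)
    done <- done + nb
  }
  ssb_over_sst <- {
    sst <- sum((y - mean(y))^2)
    ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
    ssb / sst
  }
  structure(list(statistic = "F", value = F_obs, df = c(k - 1, n - k),
                 p_parametric = stats::pf(F_obs, k - 1, n - k, lower.tail = FALSE),
                 p_perm = (1 + count) / (1 + B),
                 eta2 = ssb_over_sst,
                 n_perm = as.integer(B), n = n),
            class = "perm_test_result")
}

#' Residual-bootstrap test of a diagnosis-by-cluster interaction
#'
#' The observed interaction F from the two-way linear model (the
#' highest-order term, identical under Type II/III sums of squares) is
#' compared against null draws built by summing the reduced (main effects
#' only) model's fitted values with full-model residuals resampled with
#' replacement within each diagnosis-by-cluster cell.
#'
#' @param y numeric response (`NA` rows dropped).
#' @param diagnosis,cluster factor-like labels; all cells must be non-empty.
#' @param B bootstrap draws.
#' @param seed integer seed.
#' @return a `perm_test_result` with interaction `value` (F), `df`,
#'   `p_parametric`, `p_perm`, `etap2`.
#' @export
boot_twoway_interaction <- function(y, diagnosis, cluster, B = 2000,
                                    seed = NULL) {
  keep <- !is.na(y) & !is.na(diagnosis) & !is.na(cluster)
  y <- y[keep]
  d <- factor(diagnosis[keep])
  cl <- factor(cluster[keep])
  cell <- interaction(d, cl, drop = FALSE)
  if (any(table(cell) == 0)) stop("empty diagnosis-by-cluster cell")
  n <- length(y)
  ab <- nlevels(cell)
  df_int <- (nlevels(d) - 1) * (nlevels(cl) - 1)
  df_err <- n - ab
  if (df_err <= 0) stop("no residual degrees of freedom")
  if (!is.null(seed)) set.seed(seed)
  rows_by_cell <- split(seq_len(n), cell)
  # full model = cell means; reduced model = additive main effects
  cell_means <- vapply(rows_by_cell, function(r) mean(y[r]), numeric(1))
  X_red <- stats::model.matrix(~ d + cl)
  Q_red <- qr.Q(qr(X_red))
  rss <- function(Ystar) {
    full <- colSums(Ystar^2)
    for (rows in rows_by_cell) {
      full <- full - colSums(Ystar[rows, , drop = FALSE])^2 / length(rows)
    }
    red <- colSums(Ystar^2) - colSums(crossprod(Q_red, Ystar)^2)
    list(full = full, red = red)
  }
  r_obs <- rss(matrix(y, ncol = 1))
  F_obs <- ((r_obs$red - r_obs$full) / df_int) / (r_obs$full / df_err)
  fitted_red <- drop(Q_red %*% crossprod(Q_red, y))
  resid_full <- y - cell_means[as.integer(cell)]
  count <- 0L
  chunk <- 10000L
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    Ystar <- matrix(fitted_red, n, nb)
    for (rows in rows_by_cell) {
      vals <- resid_full[rows]
      Ystar[rows, ] <- Ystar[rows, ] +
        vals[sample.int(length(rows), length(rows) * nb, replace = TRUE)]
    }
    r_b <- rss(Ystar)
    F_b <- ((r_b$red - r_b$full) / df_int) / (r_b$full / df_err)
    F_b[is.nan(F_b)] <- 0
    count <- count + sum(F_b >= F_obs)
    done <- done + nb
  }
  ss_int <- r_obs$red - r_obs$full
  structure(list(statistic = "F", value = F_obs, df = c(df_int, df_err),
                 p_parametric = stats::pf(F_obs, df_int, df_err, lower.tail = FALSE),
                 p_perm = (1 + count) / (1 + B),
                 etap2 = ss_int / (ss_int + r_obs$full),
                 n_perm = as.integer(B), n = n),
            class = "perm_test_result")
}

# BCa interval for a two-group mean difference, stratified bootstrap,
# jackknife acceleration over the pooled sample with group labels fixed.
bca_mean_diff <- function(y1, y2, levels, B, flag_tol = 1e-12) {
  n1 <- length(y1)
  n2 <- length(y2)
  delta <- mean(y1) - mean(y2)
  t1 <- colMeans(matrix(y1[sample.int(n1, n1 * B, replace = TRUE)], n1, B))
  t2 <- colMeans(matrix(y2[sample.int(n2, n2 * B, replace = TRUE)], n2, B))
  tstar <- t1 - t2
  if (stats::sd(tstar) < flag_tol) {
    return(list(delta = delta,
                ci = matrix(delta, length(levels), 2), degenerate = TRUE))
  }
  prop <- mean(tstar < delta)
  if (prop <= 0 || prop >= 1) {
    # bootstrap distribution entirely on one side: fall back to percentile
    return(list(delta = delta,
                ci = t(vapply(levels, function(lv) {
                  stats::quantile(tstar, c((1 - lv) / 2, (1 + lv) / 2),
                                  names = FALSE)
                }, numeric(2))), degenerate = TRUE))
  }
  z0 <- stats::qnorm(prop)
  # jackknife leave-one-out estimates
  th1 <- (sum(y1) - y1) / (n1 - 1) - mean(y2)        # drop from group 1
  th2 <- mean(y1) - (sum(y2) - y2) / (n2 - 1)        # drop from group 2
  th <- c(th1, th2)
  u <- mean(th) - th
  a <- sum(u^3) / (6 * sum(u^2)^1.5)
  if (!is.finite(a)) a <- 0
  ci <- t(vapply(levels, function(lv) {
    zlo <- stats::qnorm((1 - lv) / 2)
    zhi <- -zlo
    alpha <- stats::pnorm(z0 + (z0 + c(zlo, zhi)) / (1 - a * (z0 + c(zlo, zhi))))
    stats::quantile(tstar, alpha, names = FALSE, type = 7)
  }, numeric(2)))
  list(delta = delta, ci = ci, degenerate = FALSE)
}

#' BCa pairwise mean-difference contrasts
#'
#' For every pair of groups, the mean difference and its bias-corrected and
#' accelerated (BCa) bootstrap confidence interval from group-stratified
#' resampling, reported at the nominal level and at the Bonferroni-widened
#' level `1 - (1 - level)/m` (e.g. 98.3% for three contrasts at 95%).  The
#' bias correction `z0` comes from the bootstrap CDF at the observed
#' difference and the acceleration `a` from jackknife skewness over the
#' pooled two-group sample with labels fixed.
#'
#' @param y numeric response.
#' @param labels group labels (each group >= 2 members).
#' @param level nominal confidence level.
#' @param m_corrections Bonferroni m; default = number of pairs.
#' @param B bootstrap draws per contrast.
#' @param seed integer seed.
#' @return data.frame of class `contrast_result`: one row per pair with
#'   `delta`, nominal and adjusted CI bounds, significance flags, and a
#'   `degenerate` flag for pathological bootstrap distributions.
#' @export
bca_pairwise_contrasts <- function(y, labels, level = 0.95,
                                   m_corrections = NULL, B = 2000,
                                   seed = NULL) {
  keep <- !is.na(y) & !is.na(labels)
  y <- y[keep]
  g <- factor(labels[keep])
  if (any(table(g) < 2)) stop("each group needs at least 2 members")
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  m <- m_corrections %||% length(pairs)
  adj_level <- 1 - (1 - level) / m
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(pairs, function(pr) {
    fit <- bca_mean_diff(y[g == pr[1]], y[g == pr[2]],
                         levels = c(level, adj_level), B = B)
    data.frame(group_a = pr[1], group_b = pr[2],
               delta = fit$delta,
               lower = fit$ci[1, 1], upper = fit$ci[1, 2],
               lower_adj = fit$ci[2, 1], upper_adj = fit$ci[2, 2],
               level = level, adj_level = adj_level,
               significant = fit$ci[1, 1] > 0 | fit$ci[1, 2] < 0,
               significant_adj = fit$ci[2, 1] > 0 | fit$ci[2, 2] < 0,
               degenerate = fit$degenerate,
               B = B, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Within-cluster diagnosis contrasts
#'
#' One SZ-minus-HC BCa mean-difference contrast per cluster (the post-hoc
#' follow-up to a diagnosis-by-cluster interaction), Bonferroni-adjusted for
#' the number of clusters.
#'
#' @param y numeric response.
#' @param diagnosis labels with levels SZ/HC (first level of the factor is
#'   the minuend; character input orders SZ first).
#' @param cluster cluster labels; both diagnoses must occur in each cluster.
#' @param level nominal confidence level.
#' @param B bootstrap draws.
#' @param seed integer seed.
#' @return `contrast_result` data.frame, one row per cluster.
#' @export
within_cluster_group_contrasts <- function(y, diagnosis, cluster,
                                           level = 0.95, B = 2000,
                                           seed = NULL) {
  keep <- !is.na(y) & !is.na(diagnosis) & !is.na(cluster)
  y <- y[keep]
  d <- as.character(diagnosis[keep])
  cl <- factor(cluster[keep])
  lev_d <- if (all(sort(unique(d)) == c("HC", "SZ"))) c("SZ", "HC") else unique(d)
  m <- nlevels(cl)
  adj_level <- 1 - (1 - level) / m
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(levels(cl), function(cc) {
    in_c <- cl == cc
    y1 <- y[in_c & d == lev_d[1]]
    y2 <- y[in_c & d == lev_d[2]]
    if (length(y1) < 2 || length(y2) < 2) {
      stop("cluster '", cc, "' lacks both diagnostic groups")
    }
    fit <- bca_mean_diff(y1, y2, levels = c(level, adj_level), B = B)
    data.frame(cluster = cc, group_a = lev_d[1], group_b = lev_d[2],
               delta = fit$delta,
               lower = fit$ci[1, 1], upper = fit$ci[1, 2],
               lower_adj = fit$ci[2, 1], upper_adj = fit$ci[2, 2],
               level = level, adj_level = adj_level,
               significant = fit$ci[1, 1] > 0 | fit$ci[1, 2] < 0,
               significant_adj = fit$ci[2, 1] > 0 | fit$ci[2, 2] < 0,
               degenerate = fit$degenerate, B = B,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_result", "data.frame")
  out
}
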