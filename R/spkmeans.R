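#' Per-feature between-cluster sum of squares
#'
#' Decomposes each column's total sum of squares (over non-missing entries)
#' into within- and between-cluster parts and returns the between part,
#' the score that drives the sparse k-means weight update.
#'
#' @param x numeric matrix (rows = observations), `NA` allowed.
#' @param labels cluster assignment per row (>= 2 non-empty clusters).
#' @return numeric vector of length `ncol(x)`, all `>= 0` up to rounding.
#' @export
per_feature_bcss <- function(x, labels) {
  x <- as.matrix(x)
  labels <- if (is.numeric(labels)) as.integer(labels) else as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  obs <- !is.na(x)
  storage.mode(obs) <- "double"
  x0 <- x
  x0[is.na(x)] <- 0
  nj <- colSums(obs)
  tot <- colSums(x0^2) - colSums(x0)^2 / pmax(nj, 1)
  k <- max(labels)
  ind <- matrix(0, k, nrow(x))
  ind[cbind(labels, seq_len(nrow(x)))] <- 1
  gs <- ind %*% x0
  gss <- ind %*% x0^2
  gn <- ind %*% obs
  within <- colSums(gss - gs^2 / pmax(gn, 1))
  pmax(tot - within, 0)
}

#' L1/L2-constrained weight update
#'
#' Solves `max_w sum(w * a)` subject to `||w||_2 <= 1`, `||w||_1 <= l`,
#' `w >= 0`: soft-threshold `a` and renormalize, with the threshold found by
#' binary search so the L1 constraint holds with equality when it binds.
#'
#' @param a non-negative per-feature scores (some `> 0`).
#' @param l L1 bound, `1 < l <= sqrt(length(a))`.
#' @return weight vector with `||w||_2 = 1`, `||w||_1 <= l + 1e-8`.
#' @export
update_weights <- function(a, l) {
  if (all(a <= 0)) stop("all per-feature scores are zero")
  soft <- function(delta) {
    s <- pmax(a - delta, 0)
    s / sqrt(sum(s^2))
  }
  w <- soft(0)
  if (sum(w) <= l + 1e-8) return(w)
  # bisect the threshold; the upper endpoint always satisfies ||w||_1 <= l,
  # so returning it keeps the constraint on the feasible side
  lo <- 0
  hi <- max(a)
  for (iter in 1:300) {
    mid <- (lo + hi) / 2
    s <- pmax(a - mid, 0)
    if (all(s == 0)) {
      hi <- mid
      next
    }
    l1 <- sum(s) / sqrt(sum(s^2))
    if (l1 > l) lo <- mid else hi <- mid
    if (l1 <= l && l - l1 < 1e-10) break
    if (hi - lo < 1e-15 * max(a)) break
  }
  soft(hi)
}

# NA-aware weighted Lloyd iterations from explicit initial centers.
# Distances are computed over mutually observed coordinates; the per-row
# p/m rescaling used for dissimilarities is constant across centers and so
# never changes an assignment.
weighted_lloyd <- function(x, w, centers, max_iter = 100, tol = 1e-6) {
  pre <- lloyd_precompute(x, w)
  lloyd_core(pre, w, centers, max_iter, tol)
}

# Shared precomputation for repeated Lloyd runs on the same data/weights.
lloyd_precompute <- function(x, w) {
  obs <- !is.na(x)
  storage.mode(obs) <- "double"
  x0 <- x
  x0[is.na(x)] <- 0
  list(x0 = x0, obs = obs,
       a = drop(x0^2 %*% w),                       # row term of the distance
       gm = colSums(x0) / pmax(colSums(obs), 1),
       n = nrow(x), p = ncol(x))
}

lloyd_core <- function(pre, w, centers, max_iter = 100, tol = 1e-6) {
  n <- pre$n
  k <- nrow(centers)
  x0 <- pre$x0
  obs <- pre$obs
  labels_prev <- integer(0)
  labels <- integer(n)
  wss <- NA_real_
  rows <- seq_len(n)
  for (it in seq_len(max_iter)) {
    # d[i,c] = sum_{j observed} w_j (x_ij - c_cj)^2, expanded into matrix
    # products so each iteration is BLAS-bound
    cw <- centers * rep(w, each = k)           # k x p
    d <- (-2 * (x0 %*% t(cw)) + obs %*% t(centers * cw)) + pre$a
    labels <- rep(1L, n)
    best <- d[, 1]
    for (c_i in 2:k) {
      better <- d[, c_i] < best
      if (any(better)) {
        labels[better] <- c_i
        best[better] <- d[better, c_i]
      }
    }
    repeat {  # repair empty clusters by splitting the largest cluster
      sizes <- tabulate(labels, nbins = k)
      if (all(sizes > 0)) break
      empty <- which(sizes == 0)[1]
      big <- which.max(sizes)
      members <- which(labels == big)
      far <- members[which.max(best[members])]
      labels[far] <- empty
      best[far] <- 0
    }
    wss <- sum(best)
    if (identical(labels, labels_prev)) break
    labels_prev <- labels
    ind <- matrix(0, k, n)
    ind[labels + k * (rows - 1L)] <- 1
    gs <- ind %*% x0
    gn <- ind %*% obs
    if (any(gn == 0)) {
      none <- gn == 0
      gn[none] <- 1
      centers <- gs / gn
      centers[none] <- rep(pre$gm, each = k)[none]
    } else {
      centers <- gs / gn
    }
  }
  list(labels = labels, centers = centers, wss = wss)
}

# One weighted k-means step: best partition for fixed weights over n_start
# random row-sampled initializations, plus an optional warm start from the
# previous alternation (which guarantees the objective never decreases).
# Ties in wss resolve to the lowest start index.
weighted_kmeans_step <- function(x, w, k, n_start, warm_centers = NULL) {
  n <- nrow(x)
  pre <- lloyd_precompute(x, w)
  best <- NULL
  for (s in seq_len(n_start)) {
    init <- x[sample.int(n, k), , drop = FALSE]
    if (anyNA(init)) init[is.na(init)] <- rep(pre$gm, each = k)[is.na(init)]
    fit <- lloyd_core(pre, w, init)
    if (is.null(best) || fit$wss < best$wss - 1e-12) best <- fit
  }
  if (!is.null(warm_centers)) {
    warm <- lloyd_core(pre, w, warm_centers)
    if (warm$wss < best$wss) best <- warm
  }
  best$labels
}

unweighted_centers <- function(x, labels, k) {
  obs <- !is.na(x)
  storage.mode(obs) <- "double"
  x0 <- x
  x0[is.na(x)] <- 0
  ind <- matrix(0, k, nrow(x))
  ind[cbind(labels, seq_len(nrow(x)))] <- 1
  gn <- ind %*% obs
  ctr <- (ind %*% x0) / pmax(gn, 1)
  gm <- colSums(x0) / pmax(colSums(obs), 1)
  none <- gn == 0
  if (any(none)) ctr[none] <- rep(gm, each = k)[none]
  colnames(ctr) <- colnames(x)
  ctr
}

#' Sparse k-means clustering
#'
#' Alternates (i) weighted k-means over the rows with the columns scaled by
#' `sqrt(w)` and (ii) an L1/L2-constrained update of the non-negative feature
#' weights `w` from the per-feature between-cluster sums of squares, until
#' the relative L1 change in `w` falls below `tol`.  Cluster separation is
#' thereby maximized by optimally reweighting the squared Euclidean
#' dissimilarities.  Missing cells are skipped in distances and sums of
#' squares (block-missing task data stay in the analysis).  No observation
#' trimming is performed (`alpha = 0`): this is sparse k-means, not its
#' robust trimmed variant.
#'
#' @param x numeric matrix (rows = participants, columns = task measures).
#' @param k number of clusters (`1 < k < nrow(x)`).
#' @param l sparsity bound on `||w||_1`, `1 < l <= sqrt(ncol(x))`; the
#'   default `sqrt(ncol(x))` never binds, so all features keep non-zero
#'   weights ("unconstrained" analysis mode).
#' @param n_start random center initializations evaluated at each k-means
#'   step (default 1000).
#' @param max_iter cap on weight-update alternations.
#' @param tol relative L1 convergence tolerance on `w`.
#' @param alpha trim fraction; must be 0 (argument retained so configs that
#'   request trimming fail loudly).
#' @param seed optional integer seed (solution is deterministic given it).
#' @return an object of class `sparse_kmeans`: `labels`, `weights`,
#'   `centers` (unweighted feature space), `objective` (`sum(w * BCSS)`),
#'   `objective_trace` (per alternation), `k`, `l`, `n_iter`, `converged`.
#' @export
sparse_kmeans <- function(x, k, l = sqrt(ncol(x)), n_start = 1000,
                          max_iter = 20, tol = 1e-4, alpha = 0, seed = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (alpha != 0) stop("trimmed variant not supported: alpha must be 0")
  if (k >= nrow(x)) stop("k must be smaller than the number of rows")
  if (k < 2) stop("k must be at least 2")
  if (l <= 1 || l > sqrt(p) + 1e-12) stop("l must satisfy 1 < l <= sqrt(p)")
  if (!is.null(seed)) set.seed(seed)
  w <- rep(1 / sqrt(p), p)
  labels <- NULL
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0
  warm <- NULL
  for (it in seq_len(max_iter)) {
    n_iter <- it
    labels <- weighted_kmeans_step(x, w, k, n_start, warm_centers = warm)
    warm <- unweighted_centers(x, labels, k)
    a <- per_feature_bcss(x, labels)
    w_new <- update_weights(a, l)
    trace <- c(trace, sum(w_new * a))
    if (sum(abs(w_new - w)) / sum(abs(w)) < tol) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  a <- per_feature_bcss(x, labels)
  structure(list(
    labels = labels,
    weights = w,
    centers = unweighted_centers(x, labels, k),
    objective = sum(w * a),
    objective_trace = trace,
    k = k, l = l, alpha = 0,
    n_start = n_start, n_iter = n_iter, converged = converged
  ), class = "sparse_kmeans")
}

#' @export
print.sparse_kmeans <- function(x, ...) {
  cat("Sparse k-means solution: k =", x$k,
      " l =", round(x$l, 3),
      " objective =", signif(x$objective, 6), "\n")
  cat("Cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  cat("Weights:", paste(signif(x$weights, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation-based selection of the sparsity bound
#'
#' For each candidate `l`, compares the achieved weighted between-cluster
#' objective on the observed data with its expectation under column-wise
#' permutation: `Gap(l) = log O(l) - mean_b log O_b(l)`, each permutation
#' shuffling every column independently.  Reports the gap-maximizing `l` and
#' whether the unconstrained bound `sqrt(p)` lies within one standard error
#' of the maximum (the check that an unconstrained analysis is appropriate).
#' Requires a complete matrix: run once on complete-case rows and once on a
#' kNN-imputed matrix to mirror the two tuning passes of the analysis.
#'
#' @param x complete numeric matrix.
#' @param k number of clusters.
#' @param l_grid candidate bounds in `(1, sqrt(p)]`.
#' @param n_perm number of column permutations (>= 2).
#' @param n_start starts per clustering (small values are fine here).
#' @param seed integer seed.
#' @return list with `l_grid`, `gap`, `se`, `best_l`,
#'   `unconstrained_within_1se`.
#' @export
tune_sparsity <- function(x, k, l_grid = NULL, n_perm = 25, n_start = 20,
                          seed = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("tune_sparsity needs a complete matrix (impute or drop)")
  if (n_perm < 2) stop("n_perm must be >= 2")
  p <- ncol(x)
  if (is.null(l_grid)) l_grid <- seq(1.1, sqrt(p), length.out = 8)
  if (any(l_grid <= 1 | l_grid > sqrt(p) + 1e-12)) {
    stop("l_grid must lie in (1, sqrt(p)]")
  }
  if (!is.null(seed)) set.seed(seed)
  obs_obj <- vapply(l_grid, function(l) {
    sparse_kmeans(x, k, l = l, n_start = n_start)$objective
  }, numeric(1))
  perm_obj <- matrix(NA_real_, n_perm, length(l_grid))
  for (b in seq_len(n_perm)) {
    xp <- apply(x, 2, sample)
    perm_obj[b, ] <- vapply(l_grid, function(l) {
      sparse_kmeans(xp, k, l = l, n_start = n_start)$objective
    }, numeric(1))
  }
  gap <- log(obs_obj) - colMeans(log(perm_obj))
  se <- apply(log(perm_obj), 2, stats::sd) * sqrt(1 + 1 / n_perm)
  best <- which.max(gap)
  list(l_grid = l_grid, gap = gap, se = se,
       best_l = l_grid[best],
       unconstrained_within_1se =
         gap[length(l_grid)] >= gap[best] - se[best])
}

#' Assign rows to the nearest weighted cluster center
#'
#' Each row goes to the center minimizing the weighted squared Euclidean
#' distance `sum_j w_j (x_j - c_j)^2` over the row's observed coordinates
#' (rescaled by p/m for missing cells, which never changes the argmin).
#'
#' @param rows numeric matrix (or single row) to classify.
#' @param centers k x p center matrix.
#' @param weights feature weights.
#' @return integer cluster labels.
#' @export
assign_to_centers <- function(rows, centers, weights) {
  rows <- rbind(rows)
  if (ncol(rows) != ncol(centers)) stop("dimension mismatch")
  obs <- !is.na(rows)
  x0 <- rows
  x0[!obs] <- 0
  d <- matrix(0, nrow(rows), nrow(centers))
  for (c_i in seq_len(nrow(centers))) {
    diff2 <- sweep(x0, 2, centers[c_i, ])^2
    diff2[!obs] <- 0
    d[, c_i] <- drop(diff2 %*% weights)
  }
  max.col(-d, ties.method = "first")
}
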