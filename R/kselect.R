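#' Draw a PCA-aligned uniform reference dataset
#'
#' Null reference data for cluster-number selection: the input is centered,
#' rotated onto its principal axes (right singular vectors), each rotated
#' coordinate is drawn uniformly over its observed range, and the draws are
#' rotated back and re-centered.  This is the "uniform box aligned with the
#' principal components" null (k = 1, no cluster structure).
#'
#' @param x complete numeric matrix.
#' @param n number of rows to draw (default `nrow(x)`).
#' @return matrix with `n` rows and `ncol(x)` columns.
#' @export
reference_sample <- function(x, n = nrow(x)) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("reference generation needs a complete matrix")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  v <- svd(xc, nu = 0)$v
  xr <- xc %*% v
  lo <- apply(xr, 2, min)
  hi <- apply(xr, 2, max)
  draws <- matrix(stats::runif(n * ncol(x)), n, ncol(x))
  draws <- sweep(sweep(draws, 2, hi - lo, "*"), 2, lo, "+")
  sweep(draws %*% t(v), 2, ctr, "+")
}

# Pooled within-cluster dispersion of a solution, with the feature weights of
# that solution.  plain: W = sum_r D_r/(2 n_r); weighted: divide additionally
# by (n_r - 1).  D_r is the weighted within-cluster sum of pairwise squared
# distances, i.e. D_r = 2 n_r * sum_j w_j WSS_rj over observed entries.
within_dispersion <- function(x, labels, weights, weighted = FALSE) {
  labels <- as.integer(labels)
  k <- max(labels)
  obs <- !is.na(x)
  storage.mode(obs) <- "double"
  x0 <- x
  x0[is.na(x)] <- 0
  ind <- matrix(0, k, nrow(x))
  ind[cbind(labels, seq_len(nrow(x)))] <- 1
  gs <- ind %*% x0
  gss <- ind %*% x0^2
  gn <- ind %*% obs
  wss_rj <- gss - gs^2 / pmax(gn, 1)      # k x p within-cluster SS
  per_cluster <- drop(wss_rj %*% weights)
  if (weighted) {
    sizes <- tabulate(labels, nbins = k)
    per_cluster <- per_cluster / pmax(sizes - 1, 1)
    if (any(sizes < 2)) warning("singleton cluster in weighted dispersion")
  }
  sum(per_cluster)
}

#' Gap and weighted gap statistics over a range of k
#'
#' For each k, compares the log within-cluster dispersion of the clustered
#' observed data against its mean over `B_ref` PCA-aligned uniform reference
#' datasets, each clustered the same way:
#' `gap_k = mean_b log(W_k^b) - log(W_k)`.  The weighted variant normalizes
#' each cluster's dispersion by `n_r - 1` instead of `n_r`, which makes the
#' statistic insensitive to unbalanced cluster sizes.  Standard errors are
#' `sd_b(log W_k^b) * sqrt(1 + 1/B)`.
#'
#' @param x task matrix (missing cells allowed; reference ranges come from
#'   complete-case rows).
#' @param k_range integer vector of candidate k (ascending).
#' @param B_ref number of reference datasets (>= 2).
#' @param clusterer function `(x, k) -> list(labels, weights)`; defaults to
#'   [sparse_kmeans()] with unconstrained `l` and `n_start` starts.
#' @param weighted compute the weighted variant?
#' @param n_start starts for the default clusterer.
#' @param seed integer seed.
#' @return a `gap_curve`: list with `k`, `gap`, `se`, `weighted`, `chosen_k`
#'   (by the one-standard-error rule).
#' @export
gap_statistic <- function(x, k_range = 2:10, B_ref = 50, clusterer = NULL,
                          weighted = FALSE, n_start = 20, seed = NULL) {
  x <- as.matrix(x)
  if (B_ref < 2) stop("B_ref must be >= 2")
  if (any(k_range >= nrow(x))) stop("k must be below n (singleton guard)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(clusterer)) {
    clusterer <- function(x, k) sparse_kmeans(x, k, n_start = n_start)
  }
  xc <- x[stats::complete.cases(x), , drop = FALSE]
  logW <- function(xx, k) {
    sol <- clusterer(xx, k)
    W <- within_dispersion(xx, sol$labels, sol$weights, weighted)
    if (W <= 0) stop("zero within-cluster dispersion: k too large")
    log(W)
  }
  obs_logW <- vapply(k_range, function(k) logW(x, k), numeric(1))
  ref_logW <- matrix(NA_real_, B_ref, length(k_range))
  for (b in seq_len(B_ref)) {
    xr <- reference_sample(xc, n = nrow(x))
    ref_logW[b, ] <- vapply(seq_along(k_range),
                            function(i) logW(xr, k_range[i]), numeric(1))
  }
  gap <- colMeans(ref_logW) - obs_logW
  se <- apply(ref_logW, 2, stats::sd) * sqrt(1 + 1 / B_ref)
  curve <- structure(list(k = k_range, gap = gap, se = se,
                          weighted = weighted, chosen_k = NA_integer_),
                     class = "gap_curve")
  curve$chosen_k <- choose_k_one_se(curve)
  curve
}

#' One-standard-error selection rule on a gap curve
#'
#' Chooses the smallest k whose gap value exceeds the gap of k+1 minus one
#' standard error of the gap of k+1.  The largest k cannot qualify (there is
#' no k+1 to compare against); returns `NA` when no k qualifies.
#'
#' @param curve a `gap_curve` over contiguous ascending k.
#' @return chosen k, or `NA_integer_`.
#' @export
choose_k_one_se <- function(curve) {
  k <- curve$k
  for (i in seq_len(length(k) - 1)) {
    if (curve$gap[i] > curve$gap[i + 1] - curve$se[i + 1]) return(k[i])
  }
  NA_integer_
}

#' @export
print.gap_curve <- function(x, ...) {
  cat(if (x$weighted) "Weighted gap" else "Gap", "statistic curve\n")
  print(data.frame(k = x$k, gap = round(x$gap, 4), se = round(x$se, 4)))
  cat("Chosen k (1-SE rule):", x$chosen_k, "\n")
  invisible(x)
}

# classification error rate between a predicted and an observed partition of
# the same rows, under optimal (Hungarian) matching of cluster ids.
cer <- function(labels_a, labels_b) {
  1 - matched_agreement(labels_a, labels_b) / length(labels_a)
}

# One Clest split: cluster the learning set, classify the held-out test set
# from the learning solution's weighted centers, cluster the test set
# independently, and score the disagreement.
clest_split_error <- function(x, k, clusterer, train_fraction, max_redraw = 20) {
  n <- nrow(x)
  n_train <- max(k + 1, round(train_fraction * n))
  for (attempt in seq_len(max_redraw)) {
    idx <- sample.int(n, n_train)
    test <- setdiff(seq_len(n), idx)
    if (length(test) <= k) next
    sol_train <- tryCatch(clusterer(x[idx, , drop = FALSE], k),
                          error = function(e) NULL)
    sol_test <- tryCatch(clusterer(x[test, , drop = FALSE], k),
                         error = function(e) NULL)
    if (is.null(sol_train) || is.null(sol_test)) next
    if (length(unique(sol_train$labels)) < k ||
        length(unique(sol_test$labels)) < k) next
    pred <- assign_to_centers(x[test, , drop = FALSE],
                              sol_train$centers, sol_train$weights)
    return(cer(pred, sol_test$labels))
  }
  stop("could not draw a split with k non-empty clusters on both sides")
}

#' Clest: cluster-number selection by prediction strength on resampled splits
#'
#' For each candidate k the data are repeatedly split into a learning and a
#' test set; the learning-set clustering classifies the test rows (nearest
#' weighted center) and the disagreement with an independent clustering of
#' the test set is the classification error rate.  The observed median error
#' `t_k` is compared with the same statistic on reference datasets drawn
#' under the k = 1 null: `d_k = (mean(t0) - t_k) / sd(t0)` and
#' `p_k = #(t0 <= t_k) / B_ref`.  The chosen k maximizes `d_k` among k with
#' `p_k < 0.05` and `d_k > 0`; `NA` when none qualifies.
#'
#' @param x task matrix.
#' @param k_range candidate k values.
#' @param clusterer as in [gap_statistic()].
#' @param B_obs observed-data splits per k.
#' @param B_ref number of reference datasets.
#' @param B_ref_splits splits per reference dataset.
#' @param train_fraction learning-set fraction (default 2/3).
#' @param n_start starts for the default clusterer.
#' @param seed integer seed.
#' @return a `clest_report`: per-k observed error `t_k`, reference summary,
#'   `d_k`, `p_k`, and `chosen_k`.
#' @export
clest <- function(x, k_range = 2:10, clusterer = NULL, B_obs = 200,
                  B_ref = 100, B_ref_splits = 100, train_fraction = 2 / 3,
                  n_start = 5, seed = NULL) {
  x <- as.matrix(x)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(clusterer)) {
    clusterer <- function(x, k) {
      sparse_kmeans(x, k, n_start = n_start, max_iter = 4)
    }
  }
  xc <- x[stats::complete.cases(x), , drop = FALSE]
  t_obs <- vapply(k_range, function(k) {
    stats::median(vapply(seq_len(B_obs), function(b) {
      clest_split_error(x, k, clusterer, train_fraction)
    }, numeric(1)))
  }, numeric(1))
  t_ref <- matrix(NA_real_, B_ref, length(k_range))
  for (b in seq_len(B_ref)) {
    xr <- reference_sample(xc, n = nrow(x))
    t_ref[b, ] <- vapply(k_range, function(k) {
      stats::median(vapply(seq_len(B_ref_splits), function(s) {
        clest_split_error(xr, k, clusterer, train_fraction)
      }, numeric(1)))
    }, numeric(1))
  }
  ref_mean <- colMeans(t_ref)
  ref_sd <- apply(t_ref, 2, stats::sd)
  d <- ifelse(ref_sd > 0, (ref_mean - t_obs) / ref_sd,
              ifelse(ref_mean > t_obs, Inf, -Inf))
  p <- colMeans(sweep(t_ref, 2, t_obs, "<=") )
  eligible <- which(p < 0.05 & d > 0)
  chosen <- if (length(eligible)) k_range[eligible[which.max(d[eligible])]] else NA_integer_
  structure(list(k = k_range, t_obs = t_obs, ref_mean = ref_mean,
                 ref_sd = ref_sd, d = d, p = p, chosen_k = chosen,
                 B_obs = B_obs, B_ref = B_ref, B_ref_splits = B_ref_splits),
            class = "clest_report")
}

#' @export
print.clest_report <- function(x, ...) {
  print(data.frame(k = x$k, t_obs = round(x$t_obs, 4),
                   ref_mean = round(x$ref_mean, 4),
                   d = round(x$d, 3), p = round(x$p, 4)))
  cat("Chosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' Consensus over the three cluster-number criteria
#'
#' Returns the modal choice of the gap statistic, weighted gap statistic and
#' Clest.  Ties or three-way disagreement are reported as a failed consensus
#' rather than silently picking one method.
#'
#' @param gap,wgap `gap_curve` objects (plain and weighted).
#' @param clest_report a `clest_report`.
#' @return list with `k` (NA when no consensus), `verdicts` (per method),
#'   `agreement` ("unanimous", "majority" or "none").
#' @export
select_k_consensus <- function(gap, wgap, clest_report) {
  verdicts <- c(gap = gap$chosen_k, wgap = wgap$chosen_k,
                clest = clest_report$chosen_k)
  votes <- verdicts[!is.na(verdicts)]
  if (length(votes) == 0) {
    return(list(k = NA_integer_, verdicts = verdicts, agreement = "none"))
  }
  tab <- sort(table(votes), decreasing = TRUE)
  top <- as.integer(names(tab)[1])
  agreement <- if (tab[1] == 3) "unanimous"
    else if (tab[1] == 2) "majority"
    else "none"
  if (length(tab) > 1 && tab[1] == tab[2]) agreement <- "none"
  list(k = if (agreement == "none") NA_integer_ else top,
       verdicts = verdicts, agreement = agreement)
}
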