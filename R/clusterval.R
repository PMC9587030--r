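#' Bootstrapped cluster-wise Jaccard stability
#'
#' Each resample is a bootstrap draw with duplicated rows removed; the
#' resample is reclustered with the same configuration as the original
#' solution, and each original cluster is scored by its maximum Jaccard
#' similarity (intersection over union of row-index sets, restricted to rows
#' present in the resample) over the new clusters.  Cluster-wise means over
#' the `B` resamples are labelled by the conventional thresholds: mean
#' Jaccard > 0.85 "highly stable", > 0.75 "stable", otherwise "unstable"
#' (clusters below 0.5 in an individual resample count as dissolved).
#'
#' @param x the matrix that produced `solution`.
#' @param solution a `sparse_kmeans` solution on `x`.
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @return a `stability_report`: per-cluster `mean_jaccard`, `label`,
#'   `dissolved` counts, and `B`.
#' @export
bootstrap_stability <- function(x, solution, B = 100, seed = NULL) {
  stopifnot(inherits(solution, "sparse_kmeans"))
  if (B < 1) stop("B must be >= 1")
  x <- as.matrix(x)
  n <- nrow(x)
  k <- solution$k
  if (!is.null(seed)) set.seed(seed)
  orig <- lapply(seq_len(k), function(c_i) which(solution$labels == c_i))
  jac <- matrix(NA_real_, B, k)
  for (b in seq_len(B)) {
    for (attempt in 1:20) {
      idx <- unique(sample.int(n, n, replace = TRUE))
      if (length(idx) > k) break
    }
    sol_b <- if (isTRUE(solution$fixed_weights)) {
      plain_kmeans(x[idx, , drop = FALSE], k, n_start = solution$n_start)
    } else {
      sparse_kmeans(x[idx, , drop = FALSE], k, l = solution$l,
                    n_start = solution$n_start)
    }
    new <- lapply(seq_len(k), function(c_i) idx[sol_b$labels == c_i])
    for (c_i in seq_len(k)) {
      oc <- intersect(orig[[c_i]], idx)
      jac[b, c_i] <- max(vapply(new, function(nc) {
        u <- length(union(oc, nc))
        if (u == 0) 0 else length(intersect(oc, nc)) / u
      }, numeric(1)))
    }
  }
  mean_j <- colMeans(jac)
  structure(list(
    mean_jaccard = mean_j,
    label = stability_label(mean_j),
    dissolved = colSums(jac < 0.5),
    B = B,
    cluster_sizes = tabulate(solution$labels, k)
  ), class = "stability_report")
}

#' Map mean Jaccard values to stability labels
#'
#' @param gamma numeric vector of mean Jaccard similarities in `[0, 1]`.
#' @return character vector: `"highly stable"` (> 0.85), `"stable"`
#'   (> 0.75), else `"unstable"`.
#' @export
stability_label <- function(gamma) {
  ifelse(gamma > 0.85, "highly stable",
         ifelse(gamma > 0.75, "stable", "unstable"))
}

#' @export
print.stability_report <- function(x, ...) {
  print(data.frame(cluster = seq_along(x$mean_jaccard),
                   size = x$cluster_sizes,
                   mean_jaccard = round(x$mean_jaccard, 3),
                   label = x$label,
                   dissolved = x$dissolved))
  cat("B =", x$B, "bootstrap resamples (duplicates removed)\n")
  invisible(x)
}

#' Compare two partitions of the same observations
#'
#' Classification error rate (CER; misassignment fraction under the optimal
#' Hungarian matching of cluster ids) and variation of information (VI;
#' `H(A|B) + H(B|A)` in natural-log units).  Both are zero exactly when the
#' partitions coincide up to relabeling.
#'
#' @param labels_a,labels_b label vectors of equal length, no missing values.
#' @return a `partition_comparison` list: `cer`, `vi`.
#' @export
compare_partitions <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("length mismatch")
  if (anyNA(labels_a) || anyNA(labels_b)) stop("missing labels")
  n <- length(labels_a)
  cer_v <- cer(labels_a, labels_b)
  tab <- table(labels_a, labels_b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  nz <- tab > 0
  # VI = H(A) + H(B) - 2 I(A,B)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  structure(list(cer = cer_v, vi = max(ha + hb - 2 * mi, 0)),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat("CER =", round(x$cer, 4), "  VI =", round(x$vi, 4), "nats\n")
  invisible(x)
}
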