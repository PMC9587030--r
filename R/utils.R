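# Internal utilities shared across modules.

# Derive a sub-stream seed from a master seed by a fixed offset, kept within
# the 32-bit integer range so set.seed() never overflows.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31L + offset) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve the linear assignment problem (minimum cost)
#'
#' Hungarian algorithm (shortest augmenting path formulation, O(n^2 m)).
#' Used internally to match clusters between two partitions before computing
#' classification error rates or Jaccard similarities.
#'
#' @param cost numeric matrix; rows are assigned to columns. Requires
#'   `nrow(cost) <= ncol(cost)`.
#' @return integer vector `a` of length `nrow(cost)`; row `i` is assigned to
#'   column `a[i]`, all distinct.
#' @keywords internal
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n >= 1, n <= m, all(is.finite(cost)))
  # potentials and matching; index 1 is the dummy (0) slot
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)   # p[j+1] = row matched to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

# Maximum-agreement matching of the clusters of two label vectors.
# Returns the total number of agreeing observations under the optimal
# one-to-one matching of cluster ids.
matched_agreement <- function(labels_a, labels_b) {
  tab <- table(labels_a, labels_b)
  k <- max(nrow(tab), ncol(tab))
  cost <- matrix(0, k, k)
  cost[seq_len(nrow(tab)), seq_len(ncol(tab))] <- -as.matrix(tab)
  idx <- hungarian_assign(cost)
  sum(vapply(seq_len(nrow(tab)), function(i) {
    j <- idx[i]
    if (j <= ncol(tab)) as.numeric(tab[i, j]) else 0
  }, numeric(1)))
}

# md5 of a config-like list, used for run manifests (base tools only).
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}
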