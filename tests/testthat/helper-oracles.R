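# Independent oracles used across test files.

# all permutations of a small vector (brute-force assignment oracle)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# adjusted Rand index by brute-force pair counting
ari_pairs <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# variation of information from the contingency table, written directly
vi_oracle <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  h_ab <- 0
  h_ba <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        pij <- tab[i, j] / n
        h_ab <- h_ab - pij * log(pij / (sum(tab[, j]) / n))
        h_ba <- h_ba - pij * log(pij / (sum(tab[i, ]) / n))
      }
    }
  }
  h_ab + h_ba
}

# three well-separated spherical clusters for clustering tests
make_blobs <- function(n_per = 30, p = 5, sep = 8, seed = 1) {
  set.seed(seed)
  rbind(
    matrix(rnorm(n_per * p), n_per, p),
    matrix(rnorm(n_per * p, mean = sep), n_per, p),
    matrix(rnorm(n_per * p, mean = 2 * sep), n_per, p)
  )
}

blob_truth <- function(n_per = 30) rep(1:3, each = n_per)
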