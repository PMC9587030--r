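test_that("per-feature BCSS matches trivial cases and a brute-force oracle", {
  expect_equal(per_feature_bcss(matrix(c(0, 0, 2, 2), 4, 1),
                                c("A", "A", "B", "B")), 4,
               ignore_attr = TRUE)
  expect_error(per_feature_bcss(matrix(rnorm(8), 4, 2), rep(1, 4)),
               "2 clusters")
  set.seed(2)
  for (r in 1:20) {
    m <- matrix(rnorm(18), 6, 3)
    if (r > 10) m[sample(18, 3)] <- NA
    lab <- sample(1:2, 6, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1] <- 3 - lab[1]
    oracle <- vapply(1:3, function(j) {
      v <- m[, j]
      o <- !is.na(v)
      tot <- sum((v[o] - mean(v[o]))^2)
      wi <- sum(vapply(unique(lab), function(g) {
        vg <- v[lab == g & o]
        if (length(vg) < 1) 0 else sum((vg - mean(vg))^2)
      }, numeric(1)))
      max(tot - wi, 0)
    }, numeric(1))
    expect_equal(per_feature_bcss(m, lab), oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("weight update solves the constrained soft-threshold problem", {
  expect_equal(update_weights(c(4, 0), 1.2), c(1, 0))
  # l -> 1 forces a single non-zero weight on the max coordinate
  w <- update_weights(c(3, 4), 1.000001)
  expect_lt(w[1], 1e-3)
  expect_gt(w[2], 0.999)
  # symmetric scores at l = sqrt(p) give uniform weights
  expect_equal(update_weights(rep(2, 9), 3), rep(1 / 3, 9), tolerance = 1e-8)
  # constraints hold across random cases
  set.seed(3)
  for (r in 1:50) {
    a <- runif(10) * sample(c(1, 100), 10, replace = TRUE)
    l <- runif(1, 1.01, sqrt(10))
    w <- update_weights(a, l)
    expect_equal(sum(w^2), 1, tolerance = 1e-8)
    expect_lte(sum(w), l + 1e-6)
    expect_true(all(w >= 0))
  }
  expect_error(update_weights(c(0, 0), 2), "zero")
})

test_that("sparse k-means satisfies its invariants on every run", {
  x <- make_blobs(seed = 10)
  for (s in 1:5) {
    sol <- sparse_kmeans(x, 3, n_start = 5, seed = s)
    expect_equal(sum(sol$weights^2), 1, tolerance = 1e-8)
    expect_lte(sum(sol$weights), sol$l + 1e-8)
    # objective is non-decreasing across alternations
    expect_true(all(diff(sol$objective_trace) >= -1e-8))
    # every cluster non-empty
    expect_true(all(tabulate(sol$labels, 3) > 0))
  }
  expect_error(sparse_kmeans(x, 3, l = 0.9), "l must")
  expect_error(sparse_kmeans(x, 3, alpha = 0.1), "alpha")
  expect_error(sparse_kmeans(x[1:2, ], 3), "smaller")
})

test_that("unconstrained l reproduces plain k-means with BCSS-proportional weights", {
  x <- make_blobs(seed = 20)
  sol <- sparse_kmeans(x, 3, n_start = 10, seed = 4)
  km <- kmeans(x, 3, nstart = 10, iter.max = 100, algorithm = "Lloyd")
  agree <- motivclust:::matched_agreement(sol$labels, km$cluster)
  expect_equal(agree, nrow(x))
  a <- per_feature_bcss(x, km$cluster)
  expect_equal(sol$weights, a / sqrt(sum(a^2)), tolerance = 1e-6)
})

test_that("a single informative feature collects nearly all weight at small l", {
  set.seed(3)
  x <- cbind(c(rnorm(40), rnorm(40, 4)), matrix(rnorm(80 * 9), 80, 9))
  sol <- sparse_kmeans(x, 2, l = 1.2, n_start = 20, seed = 9)
  expect_gt(sol$weights[1], 0.9)
})

test_that("solutions are deterministic given a seed and invariant to relabeling", {
  x <- make_blobs(seed = 30)
  s1 <- sparse_kmeans(x, 3, n_start = 1, seed = 5)
  s2 <- sparse_kmeans(x, 3, n_start = 1, seed = 5)
  expect_identical(s1, s2)
  # relabeling clusters leaves objective and weights unchanged
  perm <- c(3, 1, 2)
  relab <- perm[s1$labels]
  a <- per_feature_bcss(x, relab)
  expect_equal(sum(update_weights(a, s1$l) * a), s1$objective,
               tolerance = 1e-8)
})

test_that("missing cells are skipped consistently in fitting and assignment", {
  x <- make_blobs(seed = 40)
  xna <- x
  set.seed(41)
  xna[sample(length(x), round(0.1 * length(x)))] <- NA
  sol <- sparse_kmeans(xna, 3, n_start = 5, seed = 6)
  expect_equal(motivclust:::matched_agreement(sol$labels, blob_truth()),
               nrow(x))
  # assignment agrees with a brute-force weighted distance table
  rows <- xna[1:20, , drop = FALSE]
  lab <- assign_to_centers(rows, sol$centers, sol$weights)
  for (i in 1:20) {
    d <- vapply(1:3, function(c_i) {
      o <- !is.na(rows[i, ])
      sum(sol$weights[o] * (rows[i, o] - sol$centers[c_i, o])^2)
    }, numeric(1))
    expect_equal(lab[i], which.min(d))
  }
  # a zero-weight column cannot change an assignment
  w0 <- sol$weights
  w0[2] <- 0
  rows2 <- rows
  rows2[, 2] <- rows2[, 2] + 1000
  expect_equal(assign_to_centers(rows, sol$centers, w0),
               assign_to_centers(rows2, sol$centers, w0))
  # a row equal to a center gets that center's label
  expect_equal(assign_to_centers(sol$centers[2, , drop = FALSE],
                                 sol$centers, sol$weights), 2L)
  expect_error(assign_to_centers(rows[, 1:3], sol$centers, sol$weights),
               "dimension")
})

test_that("sparsity tuning finds no structure in permuted-like data and is reproducible", {
  set.seed(8)
  x <- matrix(rnorm(60 * 6), 60, 6)   # no cluster structure
  tn <- tune_sparsity(x, k = 3, l_grid = c(1.3, 1.8, sqrt(6)), n_perm = 30,
                      n_start = 3, seed = 11)
  expect_true(all(abs(tn$gap) < 3 * pmax(tn$se, 0.02)))
  tn2 <- tune_sparsity(x, k = 3, l_grid = c(1.3, 1.8, sqrt(6)), n_perm = 2,
                       n_start = 3, seed = 12)
  tn3 <- tune_sparsity(x, k = 3, l_grid = c(1.3, 1.8, sqrt(6)), n_perm = 2,
                       n_start = 3, seed = 12)
  expect_identical(tn2, tn3)
  expect_error(tune_sparsity(x, 3, n_perm = 1), "n_perm")
})

test_that("all-informative clustered data keep the unconstrained bound within 1 SE", {
  x <- make_blobs(n_per = 25, p = 6, sep = 5, seed = 50)
  tn <- tune_sparsity(x, k = 3, l_grid = seq(1.2, sqrt(6), length.out = 5),
                      n_perm = 25, n_start = 3, seed = 13)
  expect_true(tn$unconstrained_within_1se)
})
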