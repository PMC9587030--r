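test_that("rank test switches between exact and approximate forms", {
  r <- wilcoxon_mw(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_true(r$exact)
  expect_equal(wilcoxon_mw(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  big <- wilcoxon_mw(rnorm(30), rnorm(30))
  expect_false(big$exact)
  expect_error(wilcoxon_mw(numeric(0), 1:3), "empty")
})

test_that("rank test maintains its nominal size", {
  set.seed(1)
  rej <- mean(replicate(2000, {
    wilcoxon_mw(rnorm(30), rnorm(30))$p_value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("minimum-likelihood exact test is consistent with enumeration", {
  # proportional rows are exactly independent
  expect_equal(fisher_exact(rbind(c(3, 5), c(3, 5)))$p_value, 1)
  # spot-check agreement with the reference implementation
  set.seed(2)
  for (r in 1:50) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  # 2x3 agreement too
  tab3 <- matrix(c(4, 1, 3, 2, 5, 1), 2, 3)
  expect_equal(fisher_exact(tab3)$p_value, fisher.test(tab3)$p.value,
               tolerance = 1e-9)
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(fisher_exact(rbind(c(-1, 2), c(1, 2))), "non-negative")
})

test_that("conditional-MLE odds ratio matches a conditional-likelihood grid search", {
  tab <- rbind(c(7, 3), c(2, 8))
  est <- odds_ratio_cmle(tab)
  # grid-search oracle: maximize the conditional likelihood directly
  psis <- exp(seq(log(0.01), log(100), by = log(1.0005)))
  condl <- vapply(psis, function(ps) {
    x <- max(0, 9 - 10):min(9, 10)
    lf <- lchoose(10, x) + lchoose(10, 9 - x) + x * log(ps)
    f <- exp(lf - max(lf))
    (f / sum(f))[x == 7]
  }, numeric(1))
  expect_equal(est$or, psis[which.max(condl)], tolerance = 0.005)
  # proportional table: OR exactly 1, CI straddles 1
  unit <- odds_ratio_cmle(rbind(c(4, 6), c(4, 6)))
  expect_equal(unit$or, 1, tolerance = 1e-8)
  expect_lt(unit$ci[1], 1)
  expect_gt(unit$ci[2], 1)
  # estimate always inside its own CI
  expect_gte(est$or, est$ci[1])
  expect_lte(est$or, est$ci[2])
  # zero cell: one-sided bound
  zero <- odds_ratio_cmle(rbind(c(0, 5), c(4, 3)))
  expect_equal(zero$or, 0)
  expect_equal(zero$ci[1], 0)
})

test_that("Pillai trace matches the direct eigen computation and car::Manova", {
  # hand-sized example: 2 groups, 2 responses, n = 6
  Y <- rbind(c(1, 2), c(2, 1), c(1.5, 1.5), c(4, 5), c(5, 4), c(4.5, 4.6))
  g <- factor(rep(c("a", "b"), each = 3))
  pm <- pillai_manova(Y, g)
  gm <- colMeans(Y)
  H <- matrix(0, 2, 2)
  E <- matrix(0, 2, 2)
  for (lev in levels(g)) {
    Yg <- Y[g == lev, , drop = FALSE]
    d <- colMeans(Yg) - gm
    H <- H + nrow(Yg) * outer(d, d)
    E <- E + crossprod(sweep(Yg, 2, colMeans(Yg)))
  }
  expect_equal(pm$value, sum(diag(H %*% solve(H + E))), tolerance = 1e-10)
  # with covariates: agree with the car implementation
  set.seed(3)
  n <- 40
  g2 <- factor(rep(1:3, length.out = n))
  Y2 <- matrix(rnorm(n * 3), n, 3)
  cv <- matrix(rnorm(n * 2), n, 2)
  mine <- pillai_manova(Y2, g2, cv)
  ref <- car::Manova(lm(Y2 ~ cv + g2))
  ref_stats <- summary(ref)$multivariate.tests$g2
  H <- ref_stats$SSPH
  E <- ref_stats$SSPE
  expect_equal(mine$value, sum(diag(H %*% solve(H + E))), tolerance = 1e-10)
  # single response: V equals partial eta squared
  y1 <- rnorm(n)
  p1 <- pillai_manova(matrix(y1, ncol = 1), g2, cv)
  u1 <- univariate_followup(y1, g2, cv, n_perm = 0)
  expect_equal(p1$value, u1$etap2, tolerance = 1e-12)
})

test_that("Pillai V is invariant to affine rescaling of responses", {
  set.seed(4)
  Y <- matrix(rnorm(60), 20, 3)
  g <- factor(rep(1:2, 10))
  v1 <- pillai_manova(Y, g)$value
  Y2 <- Y
  Y2[, 2] <- 100 * Y2[, 2] - 7
  expect_equal(pillai_manova(Y2, g)$value, v1, tolerance = 1e-10)
})

test_that("Freedman-Lane permutation P follows the add-one convention", {
  set.seed(5)
  # groups pushed far apart: no permuted statistic can reach the observed
  y <- c(rnorm(10), rnorm(10, 50))
  g <- factor(rep(1:2, each = 10))
  fl <- freedman_lane_p(y, g, statistic = "F", n_perm = 19, seed = 6)
  expect_equal(fl$p_perm, 1 / 20)
  # P can never be zero, and with no covariates equals raw-label permutation
  expect_gt(fl$p_perm, 0)
  fl2 <- freedman_lane_p(y, g, statistic = "F", n_perm = 99, seed = 7)
  expect_gte(fl2$p_perm, 1 / 100)
  expect_error(freedman_lane_p(y, g, n_perm = 0), "n_perm")
})

test_that("Freedman-Lane MANCOVA holds its size under a real covariate effect", {
  set.seed(8)
  n <- 45
  rej <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    cv <- rnorm(n)
    Y <- matrix(rnorm(n * 2), n, 2) + cbind(1.5 * cv, -cv)  # covariate effect
    g <- factor(rep(1:3, each = 15))                         # no group effect
    fl <- freedman_lane_p(Y, g, covariates = cbind(cv), n_perm = 200)
    if (fl$p_perm < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.02)
  expect_lte(rej / n_rep, 0.09)
})

test_that("univariate follow-up reports F and the documented effect sizes", {
  r <- univariate_followup(c(0, 2, 1, 3), factor(c("a", "a", "b", "b")),
                           n_perm = 0)
  expect_equal(r$value, 0.5)
  expect_equal(r$df, c(1, 2))
  # eta2 equals etap2 with no covariates
  expect_equal(r$eta2, r$etap2)
  # eta2 ~ 1/(n-1) in expectation under the null at k = 2
  set.seed(9)
  e2 <- mean(replicate(400, {
    univariate_followup(rnorm(20), factor(rep(1:2, 10)), n_perm = 0)$eta2
  }))
  expect_lt(abs(e2 - 1 / 19), 0.02)
})
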