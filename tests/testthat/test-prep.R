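test_that("winsorization clips to type-7 quantile bounds and handles Inf", {
  # {1..40, +Inf}: the sentinel becomes max+1 = 41 before quantiles; the
  # 97.5% bound of the 41 values is 40 and the 2.5% bound is 2
  v <- c(1:40, Inf)
  w <- winsorize(v)
  expect_equal(w[41], 40)
  expect_equal(w[1], 2)
  expect_equal(w[2:40], as.numeric(2:40))
  # interior values untouched
  x <- c(5, 6, 7, 8, 9)
  expect_equal(winsorize(x, coverage = 0.6),
               pmin(pmax(x, quantile(x, 0.2, names = FALSE)),
                    quantile(x, 0.8, names = FALSE)))
  # constant vector maps to itself
  expect_equal(winsorize(rep(3, 6)), rep(3, 6))
  # rank order of finite values never changes
  set.seed(1)
  y <- c(rnorm(50), -Inf, Inf)
  wy <- winsorize(y)
  expect_equal(order(wy[1:50]), order(rank(y[1:50], ties.method = "first")))
  expect_true(all(is.finite(wy)))
  expect_error(winsorize(1:10, coverage = 1.2), "coverage")
  expect_error(winsorize(c(1, 2, Inf)), "finite")
})

test_that("power transform lambda maximizes the profile likelihood", {
  set.seed(4)
  y <- exp(rnorm(500))
  fit <- fit_power_transform(y)
  expect_equal(fit$family, "box_cox")
  # log-normal data: lambda near the log limit 0
  expect_lt(abs(fit$lambda), 0.15)
  # brute-force grid oracle over [-2, 2] step 1e-3
  grid <- seq(-2, 2, by = 1e-3)
  ll <- vapply(grid, function(l) motivclust:::power_profile_ll(l, y, NULL, "box_cox"),
               numeric(1))
  expect_lt(abs(fit$lambda - grid[which.max(ll)]), 2e-3)
  # independent implementation cross-check
  ct <- car::powerTransform(y ~ 1, family = "bcPower")
  expect_lt(abs(fit$lambda - unname(ct$lambda)), 1e-3)
})

test_that("Yeo-Johnson handles non-positive data; lambda = 1 is the identity", {
  set.seed(5)
  y <- rnorm(100)
  fit <- fit_power_transform(y)
  expect_equal(fit$family, "yeo_johnson")
  idspec <- structure(list(family = "yeo_johnson", lambda = 1),
                      class = "transform_spec")
  expect_equal(apply_power_transform(y, idspec), y, tolerance = 1e-12)
  expect_error(fit_power_transform(y, family = "box_cox"), "positive")
  # covariate-adjusted lambda: estimated against the regression residuals
  set.seed(6)
  x <- rnorm(300)
  y2 <- exp(1 + 0.8 * x + rnorm(300, 0, 0.4))
  fit_adj <- fit_power_transform(y2, design = cbind(1, x))
  expect_lt(abs(fit_adj$lambda), 0.25)
})

test_that("standardization centers and scales over non-missing entries", {
  # sample SD (n-1 denominator): {0,2} -> (x - 1)/sqrt(2)
  pm <- standardize(matrix(c(0, 2), 2, 1))
  expect_equal(drop(pm$x), (c(0, 2) - 1) / sd(c(0, 2)))
  m <- matrix(c(1, 2, NA, 10, 20, 30), 3, 2)
  pm2 <- standardize(m)
  expect_equal(colMeans(pm2$x, na.rm = TRUE), c(0, 0), ignore_attr = TRUE)
  expect_equal(apply(pm2$x, 2, sd, na.rm = TRUE), c(1, 1), ignore_attr = TRUE)
  # already standardized input is unchanged
  z <- scale(matrix(rnorm(30), 10, 3))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  expect_equal(standardize(z)$x, unclass(z), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(standardize(matrix(c(1, 1, 1), 3, 1)), "zero-variance")
})

test_that("kNN imputation uses exp(-distance) weighted neighbour averages", {
  m <- matrix(rnorm(20), 5, 4)
  expect_identical(knn_impute(m), m)
  # all neighbours share the value 7 -> imputed exactly 7
  m2 <- rbind(c(0, 7), c(0.1, 7), c(0.2, 7), c(0.3, 7), c(0.25, 7), c(0, NA))
  expect_equal(knn_impute(m2, k = 5)[6, 2], 7)
  # hand-computed two-neighbour kernel: values {0,10}, distances {1,3}
  m3 <- rbind(c(0, NA), c(1, 0), c(3, 10))
  expect_equal(knn_impute(m3, k = 2)[1, 2],
               10 * exp(-3) / (exp(-1) + exp(-3)), tolerance = 1e-12)
  expect_error(knn_impute(matrix(c(NA, 1, 1, NA), 2, 2)), "complete")
})

test_that("covariate adjustment estimates group-specific slopes", {
  set.seed(7)
  n <- 500
  diagnosis <- rep(c("SZ", "HC"), length.out = n)
  age <- round(runif(n, 20, 60))
  beta <- 0.08
  tab <- data.frame(diagnosis = diagnosis, age = age)
  # plant an SZ-specific age slope on one latent variable
  z <- matrix(rnorm(n * 10), n, 10)
  z[, 1] <- z[, 1] + ifelse(diagnosis == "SZ", beta * age, 0)
  for (j in seq_along(task_vars())) tab[[task_vars()[j]]] <- exp(z[, j] / 2)
  pm <- prepare_task_matrix(tab, covariates = "age")
  # residuals decorrelated from age within SZ
  sz <- diagnosis == "SZ"
  expect_lt(abs(cor(pm$x[sz, 1], age[sz])), 0.05)
  expect_true(pm$adjusted)
})

test_that("empty covariate list reproduces the unadjusted matrix exactly", {
  spc <- cohort_spec(seed = 3)
  tab <- inject_missingness(generate_cohort(spc), spc)
  expect_identical(prepare_task_matrix(tab)$x,
                   prepare_task_matrix(tab, covariates = character())$x)
})

test_that("zero-filled SZ-only covariates give HC rows no leverage", {
  spc <- cohort_spec(seed = 13)
  tab <- generate_cohort(spc)
  X <- motivclust:::covariate_design(
    tab$diagnosis,
    data.frame(cpz = ifelse(tab$diagnosis == "SZ", tab$cpz, 0)))
  hc <- tab$diagnosis == "HC"
  # the only non-intercept column is identically zero for HC rows
  expect_true(all(X[hc, -1] == 0))
  # missing covariate fails loudly with the column named
  expect_error(prepare_task_matrix(tab, covariates = "not_a_column"),
               "not_a_column")
})

test_that("preparation output is standardized with missing cells carried", {
  spc <- cohort_spec(seed = 21)
  tab <- inject_missingness(generate_cohort(spc), spc)
  pm <- prepare_task_matrix(tab)
  expect_true(anyNA(pm$x))  # block-missing rows stay in
  expect_lt(max(abs(colMeans(pm$x, na.rm = TRUE))), 1e-10)
  expect_lt(max(abs(apply(pm$x, 2, sd, na.rm = TRUE) - 1)), 1e-10)
  expect_true(all(is.finite(pm$x[!is.na(pm$x)])))  # sentinels winsorized away
  # refitting the transform on its own output is a no-op (lambda = 1 fits,
  # and re-centering changes nothing)
  col <- unname(pm$x[, 1][!is.na(pm$x[, 1])])
  again <- standardize(matrix(col, ncol = 1))
  expect_equal(drop(again$x), col, tolerance = 1e-10)
})
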