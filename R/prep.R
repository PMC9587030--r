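#' Winsorize a numeric vector, handling infinite sentinels
#'
#' 95% winsorization (by default): values outside the central `coverage`
#' quantile band are clipped to the band edges.  Quantiles use linear
#' interpolation of order statistics (R's type 7).  Infinite sentinels are
#' first replaced by one unit beyond the most extreme finite value so that
#' they participate in the quantile computation as the largest/smallest order
#' statistics, then clipped like any other value.
#'
#' @param values numeric vector, possibly containing `+/-Inf`; `NA`s pass
#'   through untouched.
#' @param coverage central coverage fraction in (0, 1); default 0.95.
#' @return the winsorized vector, same length and order.
#' @export
winsorize <- function(values, coverage = 0.95) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  obs <- !is.na(values)
  x <- values[obs]
  fin <- is.finite(x)
  if (sum(fin) < 3) stop("need at least 3 finite values")
  if (any(!fin)) {
    x[!fin & x > 0] <- max(x[fin]) + 1
    x[!fin & x < 0] <- min(x[fin]) - 1
  }
  tail_p <- (1 - coverage) / 2
  bounds <- stats::quantile(x, c(tail_p, 1 - tail_p), type = 7, names = FALSE)
  out <- values
  out[obs] <- pmin(pmax(x, bounds[1]), bounds[2])
  out
}

# ---- power transforms ----------------------------------------------------

# Profile log-likelihood of the Box-Cox / Yeo-Johnson model for the residuals
# of y regressed on design X (intercept-only when X is NULL).
power_profile_ll <- function(lambda, y, X = NULL, family = c("box_cox", "yeo_johnson")) {
  family <- match.arg(family)
  n <- length(y)
  z <- if (family == "box_cox") car::bcPower(y, lambda) else car::yjPower(y, lambda)
  rss <- if (is.null(X)) {
    sum((z - mean(z))^2)
  } else {
    sum(stats::lm.fit(X, z)$residuals^2)
  }
  jac <- if (family == "box_cox") {
    (lambda - 1) * sum(log(y))
  } else {
    (lambda - 1) * sum(sign(y) * log(abs(y) + 1))
  }
  -n / 2 * log(rss / n) + jac
}

#' Fit a Box-Cox or Yeo-Johnson power transform
#'
#' Estimates the transformation parameter lambda by maximizing the profile
#' log-likelihood of the (optionally covariate-adjusted) normal model: the
#' residuals of the transformed response regressed on `design` are driven
#' toward normality.  Box-Cox is used when all observed values are strictly
#' positive, Yeo-Johnson otherwise (or on request).  The search is a bounded
#' scalar maximization over lambda in [-2, 2] (tolerance 1e-5).
#'
#' @param values numeric vector (`NA` dropped for fitting).
#' @param design optional numeric model matrix (including intercept) with one
#'   row per element of `values`; `NULL` means intercept-only, which is
#'   equivalent to the unadjusted analysis.
#' @param family `"auto"` (default), `"box_cox"`, or `"yeo_johnson"`.
#' @return a `transform_spec` list: `family`, `lambda`, plus `center`/`scale`
#'   slots filled later by [standardize()].
#' @export
fit_power_transform <- function(values, design = NULL,
                                family = c("auto", "box_cox", "yeo_johnson")) {
  family <- match.arg(family)
  obs <- !is.na(values)
  y <- values[obs]
  if (length(y) < 10) stop("need at least 10 non-missing values")
  if (any(!is.finite(y))) stop("non-finite values: winsorize first")
  X <- if (!is.null(design)) as.matrix(design)[obs, , drop = FALSE]
  if (!is.null(X) && qr(X)$rank < ncol(X)) stop("singular covariate design")
  if (family == "auto") family <- if (all(y > 0)) "box_cox" else "yeo_johnson"
  if (family == "box_cox" && any(y <= 0)) {
    stop("box_cox requires strictly positive values")
  }
  opt <- stats::optimize(function(l) power_profile_ll(l, y, X, family),
                         interval = c(-2, 2), maximum = TRUE, tol = 1e-5)
  structure(list(family = family, lambda = opt$maximum,
                 center = NA_real_, scale = NA_real_),
            class = "transform_spec")
}

#' Apply a fitted power transform
#'
#' @param values numeric vector.
#' @param spec a `transform_spec` from [fit_power_transform()].
#' @return transformed values (`NA` preserved).
#' @export
apply_power_transform <- function(values, spec) {
  out <- rep(NA_real_, length(values))
  obs <- !is.na(values)
  out[obs] <- if (spec$family == "box_cox") {
    car::bcPower(values[obs], spec$lambda)
  } else {
    car::yjPower(values[obs], spec$lambda)
  }
  out
}

#' Center and scale the columns of a task matrix
#'
#' Column-wise standardization over non-missing entries (sample SD, n-1
#' denominator).  The per-column centers and scales are stored so the same
#' affine map can be reused on reference or bootstrap data.
#'
#' @param matrix numeric matrix (missing cells `NA`).
#' @param specs optional list of `transform_spec`s (one per column) to carry
#'   through with centers/scales filled in.
#' @return a `prepared_matrix`: list with `x` (standardized matrix),
#'   `transforms`, and `adjusted` flag.
#' @export
standardize <- function(matrix, specs = NULL, adjusted = FALSE) {
  x <- as.matrix(matrix)
  ctr <- colMeans(x, na.rm = TRUE)
  scl <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(scl)) || any(scl == 0)) stop("zero-variance column")
  x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  if (is.null(specs)) {
    specs <- rep(list(structure(list(family = "identity", lambda = 1,
                                     center = NA_real_, scale = NA_real_),
                                class = "transform_spec")), ncol(x))
  }
  for (j in seq_along(specs)) {
    specs[[j]]$center <- ctr[j]
    specs[[j]]$scale <- scl[j]
  }
  names(specs) <- colnames(x)
  structure(list(x = x, transforms = specs, adjusted = adjusted),
            class = "prepared_matrix")
}

#' Distance-weighted k-nearest-neighbour imputation
#'
#' Fills each missing cell with the `exp(-d)`-weighted average of the k
#' nearest complete rows, where d is the Euclidean distance over the
#' coordinates observed in the incomplete row.  Used only to build the
#' complete matrix required by the sparsity-tuning permutation path; the main
#' clustering input keeps its missing cells.
#'
#' @param matrix numeric matrix with `NA`s.
#' @param k number of neighbours (default 5).
#' @return the matrix with missing cells imputed.
#' @export
knn_impute <- function(matrix, k = 5) {
  x <- as.matrix(matrix)
  complete <- which(stats::complete.cases(x))
  if (length(complete) == 0) stop("no complete rows to impute from")
  if (k > length(complete)) stop("k exceeds the number of complete rows")
  incomplete <- which(!stats::complete.cases(x))
  for (i in incomplete) {
    obs <- which(!is.na(x[i, ]))
    if (length(obs) == 0) stop("row with no observed cells")
    d <- sqrt(colSums((t(x[complete, obs, drop = FALSE]) - x[i, obs])^2))
    nb <- complete[order(d)[seq_len(k)]]
    w <- exp(-sort(d)[seq_len(k)])
    if (sum(w) == 0) w <- rep(1, k)
    miss <- which(is.na(x[i, ]))
    x[i, miss] <- colSums(x[nb, miss, drop = FALSE] * w) / sum(w)
  }
  x
}

# Group-specific covariate design: common intercept plus one column per
# diagnosis x covariate interaction (no diagnosis main effect).  SZ-only
# covariates must already be zero-filled for HC.
covariate_design <- function(diagnosis, covariate_df) {
  n <- length(diagnosis)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (nm in colnames(covariate_df)) {
    v <- covariate_df[[nm]]
    if (anyNA(v[diagnosis == "SZ"])) stop("covariate '", nm, "' missing for an SZ row")
    sz_col <- ifelse(diagnosis == "SZ", v, 0)
    hc_col <- ifelse(diagnosis == "HC", v, 0)
    add <- cbind(sz_col, hc_col)
    colnames(add) <- paste0(nm, c(":SZ", ":HC"))
    keep <- apply(add, 2, function(col) stats::sd(col) > 0)
    X <- cbind(X, add[, keep, drop = FALSE])
  }
  if (qr(X)$rank < ncol(X)) stop("collinear covariate design")
  X
}

#' Prepare the task matrix for clustering
#'
#' Full preparation path: winsorize the persistence measure (the only one
#' with infinite sentinels) across the entire sample, fit a power transform
#' per task variable (Box-Cox when strictly positive, Yeo-Johnson otherwise),
#' optionally residualize each transformed variable on a group-specific
#' covariate design, then center and scale.  Missing cells are carried as
#' `NA` into the output; the clustering stage handles them.
#'
#' When `covariates` is non-empty the transform parameter for each variable
#' is estimated against the same interaction design used for the
#' residualization (group-specific slopes, common intercept, no diagnosis
#' main effect); SZ-only covariates are zero-filled for HC so HC fitted
#' values depend only on the intercept and HC-specific slopes.
#'
#' @param table a `cohort_table` (or any data.frame with the ten task columns
#'   and a `diagnosis` column).
#' @param covariates character vector of covariate column names (empty =
#'   unadjusted analysis).
#' @param winsor_coverage coverage for persistence winsorization.
#' @return a `prepared_matrix` with the `adjusted` flag set accordingly.
#' @export
prepare_task_matrix <- function(table, covariates = character(),
                                winsor_coverage = 0.95) {
  vars <- task_vars()
  missing_vars <- setdiff(vars, colnames(table))
  if (length(missing_vars)) stop("missing task columns: ",
                                 paste(missing_vars, collapse = ", "))
  raw <- as.matrix(table[, vars])
  # persistence is winsorized across the entire sample (it is the one
  # measure that can carry infinite sentinels)
  raw[, "apt_active_persistence"] <-
    winsorize(raw[, "apt_active_persistence"], winsor_coverage)
  X <- NULL
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, colnames(table))
    if (length(missing_cov)) stop("missing covariate column: ",
                                  paste(missing_cov, collapse = ", "))
    cov_df <- table[, covariates, drop = FALSE]
    # SZ-only covariates: zero-fill HC so the rows stay in the model
    for (nm in covariates) {
      v <- cov_df[[nm]]
      v[is.na(v) & table$diagnosis == "HC"] <- 0
      cov_df[[nm]] <- v
    }
    X <- covariate_design(table$diagnosis, cov_df)
  }
  trans <- vector("list", length(vars))
  out <- raw
  for (j in seq_along(vars)) {
    trans[[j]] <- fit_power_transform(raw[, j], design = X)
    z <- apply_power_transform(raw[, j], trans[[j]])
    if (!is.null(X)) {
      obs <- !is.na(z)
      fit <- stats::lm.fit(X[obs, , drop = FALSE], z[obs])
      z[obs] <- fit$residuals
    }
    out[, j] <- z
  }
  pm <- standardize(out, trans, adjusted = length(covariates) > 0)
  rownames(pm$x) <- if ("participant_id" %in% colnames(table)) {
    table$participant_id
  } else {
    as.character(seq_len(nrow(table)))
  }
  pm
}
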