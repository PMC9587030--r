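#' Plain (unweighted) k-means with missing-data support
#'
#' Standard k-means over rows with missing cells skipped in distances and
#' centroid updates, multi-start Lloyd iterations.  Used for the
#' groups-separated reruns (clustering data already transformed by the
#' original solution's variable weights) and as the sanity-mode clusterer
#' for the gap statistics.  Returned objects carry `fixed_weights = TRUE`
#' so stability assessment reclusters without reweighting.
#'
#' @param x numeric matrix (`NA` allowed).
#' @param k number of clusters.
#' @param n_start random initializations.
#' @param seed integer seed.
#' @return a `sparse_kmeans`-classed solution with uniform weights.
#' @export
plain_kmeans <- function(x, k, n_start = 50, seed = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (k >= nrow(x)) stop("k must be smaller than the number of rows")
  if (!is.null(seed)) set.seed(seed)
  w <- rep(1 / sqrt(p), p)
  labels <- weighted_kmeans_step(x, w, k, n_start)
  a <- per_feature_bcss(x, labels)
  structure(list(labels = labels, weights = w,
                 centers = unweighted_centers(x, labels, k),
                 objective = sum(w * a), objective_trace = sum(w * a),
                 k = k, l = sqrt(p), alpha = 0, n_start = n_start,
                 n_iter = 1L, converged = TRUE, fixed_weights = TRUE),
            class = "sparse_kmeans")
}

#' Pipeline configuration
#'
#' Bundles the knobs of the end-to-end analysis.  Defaults are desk-scale
#' resampling budgets; `paper_scale = TRUE` restores the full-scale budgets
#' (50,000-fold permutation/bootstrap, 2,000-fold stability and reference
#' sampling) used for a definitive run.
#'
#' @param k_range candidate numbers of clusters.
#' @param n_start starts for the final sparse k-means fit.
#' @param kselect_n_start starts for the (many) clusterings inside k
#'   selection.
#' @param gap_B_ref reference datasets for the gap statistics.
#' @param clest_B_obs,clest_B_ref,clest_B_ref_splits Clest budgets.
#' @param B_stability stability bootstrap resamples.
#' @param B_boot bootstrap draws for cluster-wise ANOVA/contrasts.
#' @param n_perm Freedman-Lane permutations.
#' @param covariates covariate columns for the adjusted rerun.
#' @param k_override fixed k to use when the three selection methods fail
#'   to reach a consensus (`NULL` = require consensus).
#' @param seed master seed for the whole run.
#' @param paper_scale restore full-scale budgets.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(k_range = 2:6, n_start = 50, kselect_n_start = 5,
                            gap_B_ref = 50, clest_B_obs = 100,
                            clest_B_ref = 50, clest_B_ref_splits = 20,
                            B_stability = 100, B_boot = 2000, n_perm = 2000,
                            covariates = c("age", "illness_duration", "cpz"),
                            k_override = NULL, seed = 1L,
                            paper_scale = FALSE) {
  if (paper_scale) {
    n_start <- 1000
    gap_B_ref <- 2000
    clest_B_obs <- 2000
    clest_B_ref <- 2000
    clest_B_ref_splits <- 500
    B_stability <- 2000
    B_boot <- 50000
    n_perm <- 50000
  }
  cfg <- list(k_range = k_range, n_start = n_start,
              kselect_n_start = kselect_n_start,
              gap_B_ref = gap_B_ref, clest_B_obs = clest_B_obs,
              clest_B_ref = clest_B_ref,
              clest_B_ref_splits = clest_B_ref_splits,
              B_stability = B_stability, B_boot = B_boot, n_perm = n_perm,
              covariates = covariates, k_override = k_override,
              seed = as.integer(seed))
  stopifnot(all(vapply(cfg[c("n_start", "gap_B_ref", "B_stability",
                             "B_boot", "n_perm")], function(v) v >= 1,
                       logical(1))))
  class(cfg) <- "pipeline_config"
  cfg
}

# per-cluster performance score on the prepared scale: mean of the cluster
# center with the reverse-coded measures (spatial d, switches) negated, so
# larger = better task performance
performance_score <- function(centers) {
  signs <- rep(1, ncol(centers))
  rev_vars <- c("net_spatial_d", "apt_switches")
  signs[colnames(centers) %in% rev_vars] <- -1
  drop(centers %*% signs) / ncol(centers)
}

#' Run the primary end-to-end analysis
#'
#' Executes the complete pipeline on a cohort table: task-data preparation,
#' cluster-number selection by the three criteria with consensus, the final
#' sparse k-means fit (unconstrained sparsity bound), bootstrapped cluster
#' stability, diagnosis-by-cluster contingency analysis (minimum-likelihood
#' exact test; conditional-MLE odds ratio of best-performance-cluster
#' membership), cluster-wise bootstrap ANOVAs of the primary clinical
#' measures with BCa post-hocs where the omnibus rejects, diagnosis-by-
#' cluster interaction tests with within-cluster contrasts, and a Spearman
#' correlation screen of task measures against clinical measures with
#' bootstrap-pi0 q-values.
#'
#' @param cohort a `cohort_table` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config a [pipeline_config()].
#' @param clinical_measures columns tested across clusters.
#' @return a `phenotype_run` list with all stage reports and a manifest
#'   (seed, budgets, config hash).
#' @export
run_primary <- function(cohort, config = pipeline_config(),
                        clinical_measures = c("AES", "BACS_z", "PSP", "SFS")) {
  seed <- config$seed
  pm <- prepare_task_matrix(cohort)

  kc <- function(x, k) sparse_kmeans(x, k, n_start = config$kselect_n_start,
                                     max_iter = 4)
  gap <- gap_statistic(pm$x, config$k_range, B_ref = config$gap_B_ref,
                       clusterer = kc, weighted = FALSE,
                       seed = sub_seed(seed, 101L))
  wgap <- gap_statistic(pm$x, config$k_range, B_ref = config$gap_B_ref,
                        clusterer = kc, weighted = TRUE,
                        seed = sub_seed(seed, 102L))
  cl <- clest(pm$x, config$k_range, clusterer = kc,
              B_obs = config$clest_B_obs, B_ref = config$clest_B_ref,
              B_ref_splits = config$clest_B_ref_splits,
              seed = sub_seed(seed, 103L))
  consensus <- select_k_consensus(gap, wgap, cl)
  k <- consensus$k
  if (is.na(k)) {
    if (is.null(config$k_override)) {
      stop("no consensus on k and no k_override configured")
    }
    k <- config$k_override
  }

  solution <- sparse_kmeans(pm$x, k, n_start = config$n_start,
                            seed = sub_seed(seed, 104L))
  stability <- bootstrap_stability(pm$x, solution, B = config$B_stability,
                                   seed = sub_seed(seed, 105L))

  # diagnosis x cluster composition
  comp_tab <- table(factor(cohort$diagnosis, levels = c("SZ", "HC")),
                    solution$labels)
  allocation_test <- fisher_exact(comp_tab)
  perf <- performance_score(solution$centers)
  best <- which.max(perf)
  two_by_two <- cbind(`non-best` = rowSums(comp_tab[, -best, drop = FALSE]),
                      best = comp_tab[, best])
  or_best <- odds_ratio_cmle(two_by_two)

  # cluster-wise clinical comparisons (Bonferroni over the primary set)
  m_primary <- length(clinical_measures)
  clinical <- list()
  for (i in seq_along(clinical_measures)) {
    meas <- clinical_measures[i]
    y <- cohort[[meas]]
    om <- boot_oneway_anova(y, solution$labels, B = config$B_boot,
                            seed = sub_seed(seed, 200L + i))
    posthoc <- NULL
    if (om$p_perm < 0.05 / m_primary) {
      posthoc <- bca_pairwise_contrasts(y, solution$labels,
                                        B = config$B_boot,
                                        seed = sub_seed(seed, 300L + i))
    }
    inter <- boot_twoway_interaction(y, cohort$diagnosis, solution$labels,
                                     B = config$B_boot,
                                     seed = sub_seed(seed, 400L + i))
    within <- NULL
    if (inter$p_perm < 0.05) {
      within <- within_cluster_group_contrasts(y, cohort$diagnosis,
                                               solution$labels,
                                               B = config$B_boot,
                                               seed = sub_seed(seed, 500L + i))
    }
    clinical[[meas]] <- list(omnibus = om, posthoc = posthoc,
                             interaction = inter, within_cluster = within)
  }

  # correlation screen: task measures vs clinical measures, one q-value
  # family for the whole matrix
  corr <- spearman_matrix(as.data.frame(cohort[, task_vars()]),
                          as.data.frame(cohort[, clinical_measures]))
  qv <- qvalues(corr$p, seed = sub_seed(seed, 600L))
  corr$q <- qv$q

  manifest <- list(seed = seed,
                   budgets = config[c("n_start", "gap_B_ref", "clest_B_obs",
                                      "clest_B_ref", "clest_B_ref_splits",
                                      "B_stability", "B_boot", "n_perm")],
                   k_range = config$k_range,
                   config_hash = config_hash(unclass(config)),
                   n = nrow(cohort))
  structure(list(prepared = pm, gap = gap, wgap = wgap, clest = cl,
                 consensus = consensus, k = k, solution = solution,
                 stability = stability,
                 composition = comp_tab,
                 allocation_test = allocation_test,
                 best_cluster = best, or_best_vs_rest = or_best,
                 clinical = clinical,
                 correlations = corr, pi0 = qv$pi0,
                 manifest = manifest),
            class = "phenotype_run")
}

#' @export
print.phenotype_run <- function(x, ...) {
  cat("Behavioural phenotyping run (n =", x$manifest$n, ")\n")
  cat("k verdicts:", paste(names(x$consensus$verdicts),
                           x$consensus$verdicts, sep = "=", collapse = " "),
      "->", x$k, paste0("(", x$consensus$agreement, ")"), "\n")
  print(x$solution)
  print(x$stability)
  cat("Diagnosis x cluster exact P =", signif(x$allocation_test$p_value, 3), "\n")
  print(x$or_best_vs_rest)
  invisible(x)
}

#' Groups-separated rerun
#'
#' Transforms the prepared matrix with the variable weights of the original
#' solution, splits it by diagnostic group, clusters each group separately
#' with plain k-means at the original k, and quantifies the disagreement
#' with the original partition (restricted to each group) by classification
#' error rate and variation of information.
#'
#' @param prepared `prepared_matrix` of the original run.
#' @param solution the original `sparse_kmeans` solution.
#' @param diagnosis diagnosis vector aligned with the rows.
#' @param config a [pipeline_config()].
#' @return list per group: solution, stability, `comparison` (CER/VI).
#' @export
run_groups_separated <- function(prepared, solution, diagnosis,
                                 config = pipeline_config()) {
  xw <- sweep(prepared$x, 2, sqrt(solution$weights), "*")
  out <- list()
  for (grp in unique(as.character(diagnosis))) {
    rows <- which(diagnosis == grp)
    if (length(rows) <= solution$k) stop("group '", grp, "' too small for k")
    sol_g <- plain_kmeans(xw[rows, , drop = FALSE], solution$k,
                          n_start = config$n_start,
                          seed = sub_seed(config$seed, 700L + length(out)))
    stab_g <- bootstrap_stability(xw[rows, , drop = FALSE], sol_g,
                                  B = config$B_stability,
                                  seed = sub_seed(config$seed, 710L + length(out)))
    out[[grp]] <- list(solution = sol_g, stability = stab_g,
                       comparison = compare_partitions(
                         solution$labels[rows], sol_g$labels))
  }
  out
}

#' Covariate-adjusted rerun
#'
#' Re-prepares the task data with group-specific covariate residualization
#' (SZ-only covariates zero-filled for HC), reclusters at the original k
#' with the same sparse k-means configuration, compares the adjusted
#' partition with the original one (CER/VI), and re-tests the covariates
#' and primary clinical measures across the adjusted clusters with the
#' stratified-bootstrap one-way ANOVA (covariate differences are expected
#' to be nullified; clinical cluster effects to persist).
#'
#' @param cohort the cohort table.
#' @param solution the original `sparse_kmeans` solution.
#' @param config a [pipeline_config()] (uses `covariates`).
#' @param clinical_measures columns re-tested across adjusted clusters.
#' @return list: `prepared`, `solution`, `comparison`, `covariate_tests`,
#'   `clinical_tests`.
#' @export
run_covariate_adjusted <- function(cohort, solution,
                                   config = pipeline_config(),
                                   clinical_measures = c("AES", "BACS_z",
                                                         "PSP", "SFS")) {
  pm_adj <- prepare_task_matrix(cohort, covariates = config$covariates)
  sol_adj <- sparse_kmeans(pm_adj$x, solution$k, n_start = config$n_start,
                           seed = sub_seed(config$seed, 800L))
  comparison <- compare_partitions(solution$labels, sol_adj$labels)
  sz <- cohort$diagnosis == "SZ"
  covariate_tests <- lapply(stats::setNames(config$covariates,
                                            config$covariates), function(cv) {
    v <- cohort[[cv]]
    rows <- if (all(is.na(v[!sz]))) sz else rep(TRUE, nrow(cohort))
    if (length(unique(sol_adj$labels[rows & !is.na(v)])) < 2) return(NULL)
    boot_oneway_anova(v[rows], sol_adj$labels[rows], B = config$B_boot,
                      seed = sub_seed(config$seed, 810L))
  })
  clinical_tests <- lapply(stats::setNames(clinical_measures,
                                           clinical_measures), function(meas) {
    boot_oneway_anova(cohort[[meas]], sol_adj$labels, B = config$B_boot,
                      seed = sub_seed(config$seed, 820L))
  })
  list(prepared = pm_adj, solution = sol_adj, comparison = comparison,
       covariate_tests = covariate_tests, clinical_tests = clinical_tests)
}

#' Serialize a run report to JSON
#'
#' Writes the machine-readable summary of a [run_primary()] result
#' (k verdicts, weights, cluster sizes, stability, exact tests, clinical
#' omnibus/interaction P-values, manifest) to a JSON file.
#'
#' @param run a `phenotype_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  rep <- list(
    k = run$k,
    verdicts = as.list(run$consensus$verdicts),
    agreement = run$consensus$agreement,
    cluster_sizes = tabulate(run$solution$labels, run$k),
    weights = round(run$solution$weights, 4),
    mean_jaccard = round(run$stability$mean_jaccard, 4),
    stability_labels = run$stability$label,
    allocation_p = run$allocation_test$p_value,
    best_cluster_or = run$or_best_vs_rest$or,
    best_cluster_or_ci = run$or_best_vs_rest$ci,
    clinical = lapply(run$clinical, function(cm) {
      list(omnibus_F = cm$omnibus$value, omnibus_p_boot = cm$omnibus$p_perm,
           interaction_F = cm$interaction$value,
           interaction_p_boot = cm$interaction$p_perm)
    }),
    pi0 = run$pi0,
    manifest = run$manifest
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
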