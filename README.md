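# motivclust

Multidimensional behavioural phenotyping of intrinsic motivation by sparse
k-means clustering.

## The problem

Motivational deficits are central to functional outcome in schizophrenia, but
questionnaire measures of amotivation conflate distinct facets of intrinsic
motivation. Two objective laboratory tasks separate them: a **Novelty
Exploration Task** (NET; 15-minute open field with 10 unfamiliar objects,
yielding locomotion distance, path complexity *spatial d* ∈ [1, 2], and
visual/tactile object-exploration counts and durations) and an **Activity
Preference Task** (APT; 15-minute free choice between an active and a passive
option, yielding active-engagement duration, switch count, intensity and
persistence). `motivclust` implements the full analysis pipeline for
phenotyping participants on these ten task measures and relating the
phenotypes to diagnosis (schizophrenia, SZ, vs healthy controls, HC) and
clinical scales (AES apathy, BACS cognition, PSP/SFS functioning, …).

## The method

The core is **sparse k-means** (Witten–Tibshirani style): alternate

1. weighted k-means on columns scaled by √w (Lloyd iterations, multi-start,
   missing cells skipped), and
2. the weight update w = S(a, Δ)/‖S(a, Δ)‖₂, where *a* is the vector of
   per-feature between-cluster sums of squares (BCSS), S is the non-negative
   soft-threshold, and Δ is chosen by binary search so that ‖w‖₁ ≤ l,

maximizing the weighted between-cluster separation Σⱼ wⱼ·BCSSⱼ subject to
‖w‖₂ = 1, ‖w‖₁ ≤ l. At the unconstrained bound l = √p all features keep
non-zero weights.

Around the core the package provides, as separately usable functions:

* **Preparation** — 95% winsorization (type-7 quantiles, infinite-persistence
  sentinels handled), Box-Cox/Yeo-Johnson transforms with profile-likelihood
  λ (optionally estimated against a diagnosis-by-covariate interaction
  design), standardization, distance-weighted kNN imputation.
* **Cluster-number selection** — Clest (adjusted statistic
  d_k = (mean t₀ − t_k)/sd t₀ with reference significance), the gap statistic
  and the weighted gap statistic, all against PCA-aligned uniform reference
  data, combined by consensus.
* **Validation** — bootstrapped cluster-wise Jaccard stability (resamples
  deduplicated; > 0.75 stable, > 0.85 highly stable), classification error
  rate under Hungarian matching, variation of information.
* **Inference** — minimum-likelihood exact contingency tests with
  conditional-MLE odds ratios and exact (test-inversion) CIs; Pillai-trace
  MANCOVA with Freedman-Lane permutation P; cluster-stratified bootstrap
  one-way ANOVA with nullified means; residual-bootstrap diagnosis-by-cluster
  interaction tests; BCa pairwise and within-cluster contrasts with
  Bonferroni-widened levels; Spearman screens with bootstrap-π₀ q-values and
  partial correlations.
* **Synthetic cohorts** — `cohort_spec()`/`generate_cohort()` emulate the
  two-group study design (45 SZ / 47 HC, a planted Low Exploration / Low
  Activity / High Performance structure, skewed task measures in their
  physical ranges, planted AES/PSP effects, block missingness, ±Inf
  persistence sentinels), so every stage is testable without participant
  data.

## Worked example

```r
library(motivclust)

spec   <- cohort_spec(seed = 42)                 # 45 SZ + 47 HC, 3 phenotypes
cohort <- inject_missingness(generate_cohort(spec), spec)

cfg <- pipeline_config(k_range = 2:5, gap_B_ref = 20, clest_B_obs = 40,
                       clest_B_ref = 15, clest_B_ref_splits = 10,
                       B_stability = 40, B_boot = 500, n_perm = 500,
                       n_start = 20, seed = 7)
run <- run_primary(cohort, cfg)
print(run)
```

```
Behavioural phenotyping run (n = 92 )
k verdicts: gap=3 wgap=3 clest=3 -> 3 (unanimous)
Sparse k-means solution: k = 3  l = 3.162  objective = 199.409
Cluster sizes: 30, 23, 39
Weights: 0.332, 0.323, 0.292, 0.337, 0.336, 0.303, 0.312, 0.327, 0.298, 0.299
  cluster size mean_jaccard         label dissolved
1       1   30        1.000 highly stable         0
2       2   23        0.988 highly stable         0
3       3   39        0.994 highly stable         0
B = 40 bootstrap resamples (duplicates removed)
Diagnosis x cluster exact P = 0.0671
cMLE odds ratio 2.565, 95% CI (1.035, 6.789), exact P = 0.04664
```

All three selection criteria agree on k = 3; the recovered clusters match the
planted 39/23/30 phenotype sizes and are highly stable; the diagnosis-by-
cluster allocation is not significantly imbalanced overall (exact P = 0.067),
but SZ participants have 2.57-fold odds of falling outside the
best-performance cluster (95% CI 1.04–6.79). `run$clinical` then holds the
cluster-wise bootstrap ANOVAs (the planted AES apathy elevation in the two
impaired clusters is detected) and interaction tests (the planted widening of
the SZ−HC PSP gap is detected), and `run$correlations` the q-valued Spearman
screen. `run_groups_separated()` and `run_covariate_adjusted()` reproduce the
supplementary robustness analyses.

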