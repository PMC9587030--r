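---
title: "Behavioural phenotyping of intrinsic motivation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural phenotyping of intrinsic motivation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motivclust)
```

## What the pipeline does

`motivclust` partitions participants on ten task-derived measures of
intrinsic motivation — six from a Novelty Exploration Task (NET) and four
from an Activity Preference Task (APT) — and then asks three questions of
the partition: is it stable, is it related to diagnostic group
(schizophrenia, SZ, vs healthy controls, HC), and does it carry clinical
meaning (apathy, cognition, functioning)? This vignette explains each
modelling choice, its tunable parameters, and what the accompanying tests
do and do not establish.

## Task-data preparation

Raw task measures live on bounded, skewed physical scales (distances in
metres, durations in seconds out of 900, counts out of 10, a path-geometry
exponent *spatial d* in [1, 2], and a persistence index that is infinite for
participants who used only one engagement option). Preparation proceeds:

1. **Winsorization (persistence only).** The persistence measure is 95%
   winsorized across the entire sample. The two conventions the procedure
   needs but that are genuinely open are fixed as: quantiles use linear
   interpolation of order statistics (R type 7), and ±Inf sentinels are
   replaced by one unit beyond the most extreme finite value *before* the
   quantile computation, giving them a defined total order. Winsorization
   clips to the 2.5%/97.5% bounds; by construction it never reorders finite
   values.
2. **Power transformation.** Each variable gets a Box-Cox transform when
   strictly positive, Yeo-Johnson otherwise. λ maximizes the profile
   log-likelihood of the transformed-response linear model; with no
   covariates that model is intercept-only, so λ simply normalizes the
   centered variable. The search is a bounded scalar maximization on
   λ ∈ [−2, 2] with tolerance 1e-5; the unit tests pin the optimum against a
   1e-3 grid search and against an independent implementation.
3. **Standardization.** Columns are centered and scaled (sample SD, n−1)
   over non-missing entries; centers and scales are stored for reuse on
   reference and bootstrap data.
4. **Missingness.** Task failures lose whole blocks (the four NET
   object-exploration measures, or the four APT measures). These cells are
   *kept missing* in the clustering input — distances and sums of squares
   skip them — so no participant is dropped. kNN imputation
   (five nearest complete rows, exp(−distance) weights; "distance-weighted"
   admits several kernels and this one is fixed here) is used only where a
   complete matrix is unavoidable: the sparsity-tuning permutation path.

### Covariate-adjusted preparation

The covariate-adjusted rerun replaces step 2's null model with a design
containing a common intercept plus one diagnosis × covariate interaction
column per group and covariate — group-specific slopes with **no diagnosis
main effect**, so residuals are centered around group-specific regression
lines but the SZ−HC offset itself is not removed. SZ-only covariates
(illness duration, antipsychotic dose) are zero-filled for HC: HC rows stay
in the model but cannot influence, or be influenced by, that covariate's
slope. λ is re-estimated against the same design, the transformed variable
is regressed on it, and the residuals are standardized.

## Sparse k-means

For a prepared n × p matrix (p = 10) the solution maximizes
Σⱼ wⱼ·BCSSⱼ over partitions and non-negative weights with ‖w‖₂ = 1,
‖w‖₁ ≤ l, by alternating (i) multi-start weighted Lloyd k-means on columns
scaled by √w and (ii) the closed-form soft-threshold weight update, until
the relative L1 change in w drops below `tol` (1e-4) or `max_iter`
alternations. Implementation details that matter:

* **Missing cells** are skipped in distances; the per-row p/m rescaling of
  squared dissimilarities is constant across centers, so it never changes an
  assignment (and per-feature BCSS is computed per column over observed
  entries).
* **Monotonicity.** The previous partition's centers are always included as
  a warm start in the next k-means step, so the objective trace is
  non-decreasing by construction; tests assert this per iteration.
* **Empty clusters** are repaired by splitting the largest cluster at its
  farthest member. Multi-start ties resolve to the lowest start index.
* **The inner loop** runs Lloyd iterations to a relative inertia change
  below 1e-6 (cap 100). The paper-scale configuration evaluates 1000 random
  center sets per partitioning step; the many clusterings inside
  k-selection resampling use far fewer starts (2–5), which is sufficient
  because each such fit only feeds an error-rate or dispersion statistic,
  not the final solution.
* **No trimming.** The trim fraction is fixed at α = 0 (requesting anything
  else is an error): this is sparse k-means, not its robust variant.

The sparsity bound defaults to the non-binding l = √p, on the principle
that no a-priori feature selection is wanted; `tune_sparsity()` verifies
that choice by a permutation gap curve (each permutation shuffles every
column independently), run once on complete cases and once on the
kNN-imputed matrix.

## How many clusters?

Three criteria, all comparing the observed clustering against reference
data drawn under a k = 1 null — a uniform distribution on the box aligned
with the principal components of the (complete-case) data:

* **Gap statistic**: gap(k) = mean_b log W_k^(b) − log W_k with
  W_k = Σ_r D_r/(2 n_r), D_r the weighted within-cluster sum of pairwise
  squared distances; the **weighted** variant divides by 2 n_r (n_r − 1),
  removing the cluster-size sensitivity. Selection uses the one-standard-
  error rule: the smallest k whose gap exceeds gap(k+1) − se(k+1), with
  se = sd_b(log W^(b))·√(1 + 1/B).
* **Clest**: 2/3–1/3 splits (classic Clest; the original publication's
  conventions are used where the procedure leaves them open, including the
  nearest-weighted-center classifier); the observed median classification
  error rate t_k is compared to reference medians via
  d_k = (mean t₀ − t_k)/sd t₀ and p_k = #{t₀ ≤ t_k}/B_ref; the chosen k
  maximizes d_k among {p_k < 0.05, d_k > 0}. If sd t₀ = 0, d_k is ±∞ by the
  sign of the numerator.
* **Consensus**: the modal choice of the three; ties and three-way
  disagreement are reported, never silently resolved.

Default budgets are desk-scale (B_ref ≈ 50–100, B_obs ≈ 100–200 splits)
and Monte-Carlo consistent; `pipeline_config(paper_scale = TRUE)` restores
the definitive 2000/2000/500-fold budgets.

## Stability and partition agreement

Bootstrap resamples (duplicates removed — "omitting multiple points") are
reclustered with the original configuration; each original cluster scores
its best Jaccard match among the new clusters, restricted to rows present
in the resample (the resample-restricted convention is a deliberate choice;
the alternative against full original clusters penalizes sampling loss).
Mean Jaccard > 0.75 is labelled stable, > 0.85 highly stable. Partition
agreement uses the classification error rate under optimal Hungarian
matching and the variation of information H(A|B) + H(B|A) in nats; VI is a
true metric, which the tests exercise on random triples.

## Resampling inference

* **Exact contingency tests** enumerate all tables with the observed
  margins; P sums the probabilities not exceeding the observed table's
  (minimum-likelihood two-sided convention, relative slack 1e-7 against
  floating-point ties). The 2 × 2 odds ratio is the conditional MLE under
  Fisher's noncentral hypergeometric, and its CI inverts the same
  minimum-likelihood test — the pairing that reproduces the published
  interval, where the central-CI convention does not.
* **Freedman-Lane permutation** for group effects with covariates: permute
  reduced-model residuals, add them to reduced fitted values, recompute
  Pillai's V (or F) from the full model. Empirical P uses the add-one
  convention (1 + r)/(1 + B) and can never be zero.
* **Cluster-stratified bootstrap ANOVA**: "between-cluster mean differences
  nullified" is implemented as centering each cluster on the grand mean,
  which preserves within-cluster distributions exactly, then resampling
  within cluster with sizes fixed.
* **Interaction bootstrap**: null responses = additive-model fitted values
  plus full-model residuals resampled within diagnosis × cluster cells; the
  interaction F uses the highest-order-term SS (Type II ≡ Type III here).
* **BCa contrasts**: group-stratified resampling; bias correction z₀ from
  the bootstrap CDF at the observed difference; acceleration from jackknife
  skewness over the pooled sample with labels fixed; reported at the
  nominal level and the Bonferroni-widened level 1 − (1 − level)/m
  (98.3% for m = 3). Degenerate bootstrap distributions collapse to a
  flagged point interval. B defaults to 2000 for contrasts (the source
  analyses state 50,000 only for null-F generation; the contrast B is a
  package choice).
* **q-values**: Storey-type, π₀ estimated over the λ grid 0.05…0.95 by
  minimizing the bootstrap MSE (100 draws) around the lower decile of the
  plug-in curve — the decile target is markedly more stable than the
  minimum on small families. One q-value family per correlation matrix.

## The synthetic cohort generator

`generate_cohort()` is a first-class, tested module, not a fixture. It
draws latent Gaussian performance scores around three cluster centers that
follow the qualitative Low Exploration / Low Activity / High Performance
pattern (LE: −0.6 SD on NET; LA: −0.6 SD on APT; HP: +0.6 SD on both,
scaled by `separation`, default 3), then maps them through exp/affine
transforms into the physical ranges — guaranteeing the positive skew that
makes the Box-Cox step non-trivial — with counts rounded and clipped and
the two reverse-coded measures (spatial d, switches) flipped. Cluster
proportions default to 39/23/30 of 92 and within-cluster SZ shares to
20/39, 15/23, 10/30, mirroring the published composition; magnitudes of the
centers are free parameters of the generator, not estimates of unpublished
means. Clinical scores plant a cluster main effect on AES (0.8 SD,
LE/LA above HP) and diagnosis-by-cluster interactions on AES (0.4 SD) and
PSP (0.8 SD, the SZ−HC gap widening HP→LA→LE); these magnitudes were chosen
once so that a cohort of 92 gives conventional ~80–90% power for the
corresponding tests, matching the detectability the published analyses
imply. Block missingness (default 2% of rows) and two infinite-persistence
sentinels emulate the recorded failure modes. One master seed drives fixed
sub-streams, so identical specs give byte-identical CSVs.

What the generator does **not** emulate: real within-task correlation
structure beyond the cluster factor, floor/ceiling pile-ups, ordinal scale
granularity, or diagnosis differences in task variance. Passing
recovery tests therefore show that the pipeline detects the structure it
targets at realistic sizes and noise — not that the published participant
data would yield the same numbers.

## Problem sizes and numerical choices

The shipped tests run at reduced Monte-Carlo budgets chosen as the package's
own desk-scale defaults: k-selection recovery uses 20 replicate cohorts
(gap/weighted-gap with 50 reference sets; Clest with 100 observed splits and
50 × 20 reference splits over k ∈ 2…5); calibration checks use 500 null
simulations at B = 500–1000; BCa coverage uses 1000 simulations at B = 2000.
Estimates at these sizes are Monte-Carlo consistent with the full-scale
budgets, with wider intervals. Other fixed numerics: weight-update binary
search to |‖w‖₁ − l| < 1e-8; Lloyd convergence on label fixity; Clest
splits redrawn (up to 20 times) when either side loses a cluster;
reference-data generation tolerates rank-deficient input by drawing
zero-range coordinates as constants.

## Known limitations

* Clest is expensive at paper-scale budgets; the desk-scale defaults trade
  Monte-Carlo precision for tractability.
* The exact 2 × C enumeration is designed for C ≤ 3 and n ≤ ~100 (the
  regime of this design); no Monte-Carlo fallback is provided.
* BCa intervals can misbehave when the bootstrap distribution is one-sided
  or degenerate; such intervals are flagged rather than silently reported.
* The covariate-adjusted rerun assumes linear covariate effects on the
  transformed scale.
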