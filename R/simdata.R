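#' Specify a synthetic behavioural-phenotyping cohort
#'
#' Defines the generative model for a two-group (schizophrenia SZ / healthy
#' control HC) cohort with a planted three-cluster structure in the ten
#' task-derived behavioural measures: six from a 15-minute Novelty Exploration
#' Task (NET; locomotion distance and spatial d, visual and tactile object
#' exploration counts and durations) and four from a 15-minute Activity
#' Preference Task (APT; active engagement duration, switches, intensity,
#' persistence).
#'
#' The three planted phenotypes follow the qualitative center pattern of the
#' study design this generator emulates: a Low Exploration cluster (LE; poor
#' NET performance, intermediate APT), a Low Activity cluster (LA; poor APT,
#' intermediate NET) and a High Performance cluster (HP; good performance on
#' both tasks).  Raw task measures are produced on a latent Gaussian scale and
#' mapped through exponential/affine transforms into their physical ranges, so
#' they are positively skewed and the Box-Cox preparation step downstream is
#' non-trivial.
#'
#' @param n_sz,n_hc number of SZ and HC participants (defaults 45 and 47).
#' @param cluster_proportions length-3 simplex weights for the LE, LA and HP
#'   clusters; defaults to the 39/23/30 split of 92.
#' @param composition per-cluster probability that a member is SZ; defaults
#'   20/39, 15/23, 10/30.
#' @param separation non-negative scalar multiplying the between-cluster
#'   center offsets, in latent SD units.  `0` collapses all cluster centers.
#' @param skew non-negative scalar multiplying the per-variable log-normal
#'   shape parameters; `0` removes skew entirely.
#' @param noise_sd latent within-cluster noise SD (default 1).
#' @param clinical_effects list with elements `aes_cluster`,
#'   `aes_interaction`, `psp_interaction` (standardized effect magnitudes, in
#'   units of the scale's residual SD) controlling the planted Apathy
#'   Evaluation Scale cluster main effect and the AES/PSP diagnosis-by-cluster
#'   interactions.
#' @param age_effect latent-SD change in task performance per SD of age
#'   (default 0; set non-zero to plant an age confound for the
#'   covariate-adjusted rerun to remove).
#' @param missing_rate fraction of rows in `[0, 1)` receiving a jointly
#'   missing task block (half NET object-exploration, half APT).
#' @param n_inf_persistence number of participants whose APT active
#'   persistence is the infinite sentinel (alternating `+Inf`/`-Inf`),
#'   emulating participants who engaged in only one engagement option.
#' @param seed integer master seed; all sub-streams derive from it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_sz = 45, n_hc = 47,
                        cluster_proportions = c(39, 23, 30) / 92,
                        composition = c(20 / 39, 15 / 23, 10 / 30),
                        separation = 3,
                        skew = 1,
                        noise_sd = 1,
                        clinical_effects = list(aes_cluster = 0.8,
                                                aes_interaction = 0.4,
                                                psp_interaction = 0.8),
                        age_effect = 0,
                        missing_rate = 0.02,
                        n_inf_persistence = 2,
                        seed = 1L) {
  if (n_sz < 0 || n_hc < 0) stop("participant counts must be non-negative")
  if (length(cluster_proportions) != 3 ||
      any(cluster_proportions < 0) ||
      abs(sum(cluster_proportions) - 1) > 1e-12) {
    stop("cluster_proportions must be 3 non-negative weights summing to 1")
  }
  if (separation < 0) stop("separation must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  defaults <- list(aes_cluster = 0.8, aes_interaction = 0.4, psp_interaction = 0.8)
  clinical_effects <- utils::modifyList(defaults, as.list(clinical_effects))
  structure(list(
    n_sz = as.integer(n_sz), n_hc = as.integer(n_hc),
    cluster_proportions = cluster_proportions,
    composition = composition,
    separation = separation, skew = skew, noise_sd = noise_sd,
    clinical_effects = clinical_effects,
    age_effect = age_effect,
    missing_rate = missing_rate,
    n_inf_persistence = as.integer(n_inf_persistence),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# The ten task measures, in fixed column order.
task_vars <- function() {
  c("net_distance", "net_spatial_d", "net_visobj_count", "net_visobj_time",
    "net_tacobj_count", "net_tacobj_time",
    "apt_active_time", "apt_switches", "apt_active_intensity",
    "apt_active_persistence")
}

# Latent cluster center directions on the "performance" orientation
# (higher latent value = better performance on every measure; the physical
# mapping reverses spatial d and switches).  Rows: LE, LA, HP.
cluster_center_pattern <- function() {
  net <- c("net_distance", "net_spatial_d", "net_visobj_count",
           "net_visobj_time", "net_tacobj_count", "net_tacobj_time")
  apt <- c("apt_active_time", "apt_switches", "apt_active_intensity",
           "apt_active_persistence")
  m <- matrix(0, 3, 10, dimnames = list(c("LE", "LA", "HP"), task_vars()))
  m["LE", net] <- -0.6
  m["LA", apt] <- -0.6
  m["HP", ] <- 0.6
  m
}

#' Generate a synthetic cohort
#'
#' Draws a participant table from a [cohort_spec()]: planted cluster
#' membership, diagnosis composition within cluster, demographics, SZ-only
#' covariates (illness duration, chlorpromazine-equivalent dose), clinical
#' scales with the planted AES cluster main effect and AES/PSP
#' diagnosis-by-cluster interactions, and the ten positively skewed task
#' measures in their physical ranges.  Identical spec (including seed) yields
#' an identical table.
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` (class `cohort_table`) with one row per participant
#'   and a `true_cluster` column recording the planted label.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_sz + spec$n_hc
  vars <- task_vars()

  # --- membership and diagnosis ------------------------------------------
  set.seed(sub_seed(spec$seed, 11L))
  # deterministic target counts per cluster (largest remainder), then the
  # SZ/HC split within cluster follows the composition parameter as closely
  # as the group totals allow.
  target <- floor(spec$cluster_proportions * n)
  rem <- n - sum(target)
  if (rem > 0) {
    frac <- spec$cluster_proportions * n - target
    target[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      target[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  sz_target <- round(target * spec$composition)
  # repair rounding so SZ totals match n_sz
  excess <- sum(sz_target) - spec$n_sz
  i <- 1L
  while (excess != 0) {
    c_i <- ((i - 1L) %% 3L) + 1L
    step <- -sign(excess)
    cand <- sz_target[c_i] + step
    if (cand >= 0 && cand <= target[c_i]) {
      sz_target[c_i] <- cand
      excess <- excess + step
    }
    i <- i + 1L
  }
  cluster <- rep(c("LE", "LA", "HP"), times = target)
  diagnosis <- unlist(lapply(1:3, function(c_i) {
    d <- rep("HC", target[c_i])
    if (sz_target[c_i] > 0) d[seq_len(sz_target[c_i])] <- "SZ"
    d
  }))
  ord <- sample.int(n)            # shuffle row order
  cluster <- cluster[ord]
  diagnosis <- diagnosis[ord]

  # --- demographics and covariates ---------------------------------------
  set.seed(sub_seed(spec$seed, 23L))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.39, 0.61))
  age <- round(runif(n, 20, 58))
  illness_duration <- ifelse(diagnosis == "SZ",
                             round(rgamma(n, shape = 2.2, scale = 5) + 1), NA)
  cpz <- ifelse(diagnosis == "SZ",
                round(exp(rnorm(n, log(430), 0.55)) / 10) * 10, NA)

  # --- latent task performance -------------------------------------------
  set.seed(sub_seed(spec$seed, 37L))
  centers <- cluster_center_pattern() * spec$separation
  z <- centers[cluster, , drop = FALSE] +
    matrix(rnorm(n * 10, sd = spec$noise_sd), n, 10,
           dimnames = list(NULL, vars))
  if (spec$age_effect != 0) {
    z <- z + spec$age_effect * ((age - mean(age)) / stats::sd(age))
  }

  # --- map latent scale to physical ranges -------------------------------
  s <- spec$skew
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  tab <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    diagnosis = diagnosis, sex = sex, age = age,
    illness_duration = illness_duration, cpz = cpz,
    stringsAsFactors = FALSE
  )
  tab$net_distance <- 30 * exp(0.40 * s * z[, "net_distance"])
  # spatial d reversed: better performance = straighter paths (d near 1)
  tab$net_spatial_d <- clip(1.5 - 0.12 * z[, "net_spatial_d"], 1, 2)
  tab$net_visobj_count <- clip(round(6 + 1.5 * z[, "net_visobj_count"]), 0, 10)
  tab$net_visobj_time <- clip(120 * exp(0.50 * s * z[, "net_visobj_time"]), 0, 900)
  tab$net_tacobj_count <- clip(round(4 + 1.5 * z[, "net_tacobj_count"]), 0, 10)
  tab$net_tacobj_time <- clip(60 * exp(0.55 * s * z[, "net_tacobj_time"]), 0, 900)
  tab$net_visobj_time[tab$net_visobj_count == 0] <- 0
  tab$net_tacobj_time[tab$net_tacobj_count == 0] <- 0
  tab$apt_active_time <- clip(300 * exp(0.35 * s * z[, "apt_active_time"]), 0, 900)
  # switches reversed: frequent switching = poor sustained engagement
  tab$apt_switches <- clip(round(8 * exp(-0.30 * s * z[, "apt_switches"])), 0, Inf)
  tab$apt_active_intensity <- 0.5 * exp(0.30 * s * z[, "apt_active_intensity"])
  tab$apt_active_persistence <- 1.2 * exp(0.45 * s * z[, "apt_active_persistence"])

  # --- clinical scales ----------------------------------------------------
  set.seed(sub_seed(spec$seed, 51L))
  eff <- spec$clinical_effects
  sz <- diagnosis == "SZ"
  # AES (apathy, higher = worse): diagnosis gap + cluster main effect
  # (LE, LA elevated vs HP) + a diagnosis-by-cluster interaction.
  aes_sd <- 6
  aes_cluster_shift <- c(LE = 0.5, LA = 0.5, HP = -1)[cluster] * eff$aes_cluster * aes_sd
  aes_int <- c(LE = 0.5, LA = -0.5, HP = 0.25)[cluster] * eff$aes_interaction * aes_sd
  tab$AES <- round(ifelse(sz, 32, 24) + aes_cluster_shift + ifelse(sz, aes_int, 0) +
                     rnorm(n, 0, aes_sd))
  # PSP (functioning, higher = better): SZ deficit widening HP -> LA -> LE.
  psp_sd <- 9
  psp_gap <- -(18 + c(LE = 1, LA = 0, HP = -1)[cluster] * eff$psp_interaction * psp_sd)
  tab$PSP <- round(clip(80 + ifelse(sz, psp_gap, 0) + rnorm(n, 0, psp_sd), 1, 100))
  tab$BACS_z <- round(ifelse(sz, -1.1, 0.45) + rnorm(n, 0, 0.9), 2)
  tab$SFS <- round(ifelse(sz, 112, 122) + rnorm(n, 0, 7), 2)
  tab$SANS_total <- ifelse(sz, pmax(0, round(17 + rnorm(n, 0, 9))), NA)
  tab$SANS_amot <- ifelse(sz, pmax(0, round(12 + rnorm(n, 0, 6))), NA)
  tab$TEPS_ant <- round(45 + rnorm(n, 0, 7))
  tab$TEPS_con <- round(ifelse(sz, 37, 39) +
                          c(LE = -0.3, LA = -0.3, HP = 0.6)[cluster] * 3 +
                          rnorm(n, 0, 5))
  tab$BIS <- round(ifelse(sz, 63, 53) + rnorm(n, 0, 8))
  tab$BAI <- pmax(0, round(ifelse(sz, 9, 3) + rnorm(n, 0, 5)))
  tab$novelty_score <- round(runif(n, 3, 9), 1)
  tab$interest_score <- round(runif(n, 2, 8), 1)
  tab$finger_tapping <- round(ifelse(sz, 95, 105) + rnorm(n, 0, 12))
  tab$true_cluster <- cluster
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Inject block-wise missingness and infinite-persistence sentinels
#'
#' Emulates the two real failure modes of the tasks: head-marker loss makes
#' the four NET object-exploration measures jointly unavailable, and APT
#' recording failure makes the four APT measures jointly unavailable.
#' Participants who used only one engagement option get an infinite
#' persistence sentinel (`+Inf`/`-Inf`, alternating) rather than a missing
#' value.
#'
#' @param table a `cohort_table`.
#' @param spec the [cohort_spec()] that generated it (uses `missing_rate`,
#'   `n_inf_persistence` and `seed`).
#' @return the table with whole task blocks set to `NA` and persistence
#'   sentinels applied.
#' @export
inject_missingness <- function(table, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(table)
  net_block <- c("net_visobj_count", "net_visobj_time",
                 "net_tacobj_count", "net_tacobj_time")
  apt_block <- c("apt_active_time", "apt_switches", "apt_active_intensity",
                 "apt_active_persistence")
  set.seed(sub_seed(spec$seed, 77L))
  n_miss <- round(spec$missing_rate * n)
  if (n_miss > 0) {
    rows <- sample.int(n, n_miss)
    half <- ceiling(n_miss / 2)
    table[rows[seq_len(half)], net_block] <- NA
    if (n_miss > half) table[rows[(half + 1):n_miss], apt_block] <- NA
  }
  if (spec$n_inf_persistence > 0) {
    ok <- which(!is.na(table$apt_active_persistence))
    rows <- sample(ok, min(spec$n_inf_persistence, length(ok)))
    signs <- rep(c(Inf, -Inf), length.out = length(rows))
    table$apt_active_persistence[rows] <- signs
  }
  table
}

#' Write / read a cohort table as CSV
#'
#' RFC-4180 CSV, UTF-8, header row, missing cells empty, infinite persistence
#' sentinels serialized as `"inf"` / `"-inf"`.  Writing the same table twice
#' produces byte-identical files.
#'
#' @param table a `cohort_table`.
#' @param path file path.
#' @return `write_cohort`: `path`, invisibly. `read_cohort`: a `cohort_table`.
#' @export
write_cohort <- function(table, path) {
  out <- as.data.frame(table)
  p <- out$apt_active_persistence
  pc <- formatC(p, digits = 15, format = "g")
  pc[!is.finite(p) & !is.na(p)] <- ifelse(p[!is.finite(p) & !is.na(p)] > 0, "inf", "-inf")
  pc[is.na(p)] <- NA
  out$apt_active_persistence <- pc
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\r\n")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  p <- tab$apt_active_persistence
  num <- suppressWarnings(as.numeric(p))
  num[p %in% "inf"] <- Inf
  num[p %in% "-inf"] <- -Inf
  tab$apt_active_persistence <- num
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
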