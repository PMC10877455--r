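#' One replicate of the null FWE calibration experiment
#'
#' Generates a cohort of pure-noise measure maps (white Gaussian voxel
#' noise smoothed with the pipeline's 8-mm kernel — no group effect
#' anywhere), draws unrelated demographic covariates, residualizes, and
#' runs the two directional cluster-FWE tests. Under the null, the
#' probability that any cluster survives should equal the cluster-level
#' alpha in each direction; repeating this over seeds estimates the
#' family-wise false-positive rate of [cluster_fwe()].
#'
#' Noise maps stand in for computed measure maps here because calibration
#' only depends on the exchangeability of the per-subject maps, which the
#' no-effect simulator guarantees by construction; this keeps hundreds of
#' replicates tractable.
#'
#' @param seed Integer seed for this replicate.
#' @param grid A [volume_grid()]; default 24^3 at 4 mm.
#' @param n_per_group Subjects per group.
#' @param smooth_fwhm_mm Map smoothness in mm.
#' @param n_perm Permutations for the FWE null.
#' @param alpha_cluster Cluster-level threshold.
#' @return Named logical vector: did any cluster survive in the decrease /
#'   increase direction?
#' @export
null_fwe_replicate <- function(seed, grid = volume_grid(c(24, 24, 24), 4),
                               n_per_group = 60, smooth_fwhm_mm = 8,
                               n_perm = 500, alpha_cluster = 0.05) {
  V <- prod(grid$shape); N <- 2 * n_per_group
  sim <- .with_seed(seed, {
    Y <- matrix(0, V, N)
    for (i in seq_len(N))
      Y[, i] <- as.vector(smooth_map(array(rnorm(V), grid$shape),
                                     smooth_fwhm_mm, grid))
    cov <- data.frame(age = runif(N, 45, 80), sex = rbinom(N, 1, 0.5),
                      tiv_ml = rnorm(N, 1500, 120))
    list(Y = Y, cov = cov)
  })
  Yr <- residualize(sim$Y, sim$cov)
  grp <- rep(c(TRUE, FALSE), each = n_per_group)
  res <- cluster_fwe(Yr, grp, grid, c("decrease", "increase"),
                     alpha_cluster = alpha_cluster, n_perm = n_perm,
                     seed = seed + 500000L)
  c(decrease = any(res$decrease$mask), increase = any(res$increase$mask))
}

#' Simulation configuration of the planted-effect recovery experiment
#'
#' The cohort used to test end-to-end recovery of criterion-linked
#' functional decreases: a 16^3 grid at 4 mm, 120 timepoints at TR
#' 0.735 s, 260 cases / 120 controls, flat-ish correlated criteria
#' (loading 0.75) so that enough criteria constellations clear the
#' 10-participant floor at desk scale, and a single spherical region
#' (radius 3.5 voxels) in which in-band signal amplitude is reduced by
#' 0.10 for each of the antidepressant-use and ICD-10 criteria met —
#' the two criteria the analysis should single out.
#'
#' The case count (340) is sized so that enough distinct constellations
#' clear the 10-member floor to separate the planted criteria from their
#' correlates: with too few retained constellations, a correlated
#' criterion can share exactly the planted criteria's retained-membership
#' pattern and become indistinguishable in attribution.
#'
#' @param seed Integer seed for the cohort.
#' @return A [sim_config()].
#' @export
recovery_config <- function(seed) {
  grid <- volume_grid(c(16, 16, 16), 4)
  sim_config(seed = seed, grid = grid, n_timepoints = 120,
             n_cases = 340, n_controls = 120,
             prevalence = c(helpseek = 0.60, selfrep = 0.50, antidep = 0.42,
                            smith = 0.34, icd10 = 0.30, cidisf = 0.26),
             criteria_loading = 0.75,
             effect_regions = list(
               effect_region(c(8, 8, 8), 3.5, baseline_amp = 1,
                             func_amp = c(0, 0, -0.10, 0, -0.10, 0))))
}

#' One replicate of the planted-effect recovery experiment
#'
#' Simulates the [recovery_config()] cohort, computes smoothed fALFF maps,
#' runs the stage-1 battery against the control pool, extracts stratum and
#' constellation effect sizes over the surviving decrease masks, and
#' attributes them to criteria. Returns the replicate's verdicts:
#'
#' * `dice_union` — Dice overlap between the union of the decrease masks
#'   and the planted sphere;
#' * `monotone` — for every decrease mask, Spearman correlation between
#'   exact-k and |d| above 0.7 (effects grow with restrictiveness);
#' * `ranking_ok` — on every decrease mask with all six deltas defined,
#'   the two most negative difference-in-effect-size values belong to the
#'   antidepressant-use and ICD-10 criteria.
#'
#' @param seed Integer seed for this replicate.
#' @param n_perm Permutations for stage 1.
#' @param min_n Minimum constellation size.
#' @return List with the verdicts plus the underlying tables.
#' @export
recovery_replicate <- function(seed, n_perm = 199, min_n = 10) {
  cfg <- recovery_config(seed)
  g <- cfg$grid
  subjects <- simulate_cohort(cfg)
  stacks <- simulate_measure_stack(cfg, subjects, "falff", smooth_fwhm_mm = 8)
  s1 <- run_stage1(stacks, subjects, g, "pool", n_perm = n_perm,
                   seed = seed + 900000L)
  dec <- s1$masks[grepl("decrease", names(s1$masks))]
  sphere <- sphere_mask(g, c(8, 8, 8), 3.5)
  if (!length(dec)) {
    return(list(dice_union = 0, monotone = FALSE, ranking_ok = FALSE,
                n_decrease_masks = 0L))
  }
  union_mask <- Reduce(`|`, dec)
  dice_union <- 2 * sum(union_mask & sphere) / (sum(union_mask) + sum(sphere))

  mm <- mask_means_by_modality(stacks, dec)
  effk <- suppressMessages(
    effect_table(subjects, mm, "strata", min_n = min_n, ci = FALSE))
  monotone <- all(vapply(split(effk, effk$mask_id), function(s) {
    nrow(s) >= 3 && cor(s$k, abs(s$d), method = "spearman") > 0.7
  }, TRUE))

  effc <- suppressMessages(
    effect_table(subjects, mm, "constellations", min_n = min_n, ci = FALSE))
  at <- attribute_criteria(effc)
  ranking_ok <- all(vapply(split(at, at$mask_id), function(s) {
    if (any(is.na(s$delta_es))) return(FALSE)
    setequal(s$criterion[order(s$delta_es)][1:2], c("antidep", "icd10"))
  }, TRUE))

  list(dice_union = dice_union, monotone = monotone, ranking_ok = ranking_ok,
       n_decrease_masks = length(dec), strata_effects = effk,
       constellation_effects = effc, attribution = at)
}
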