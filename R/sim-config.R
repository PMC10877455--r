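#' Specify a planted-effect region for the cohort simulator
#'
#' A spherical region in which subject volumes carry signal. In functional
#' volumes every subject receives an in-band oscillation of amplitude
#' `baseline_amp + sum(func_amp[criteria met])` (floored at 0), so negative
#' per-criterion amplitudes model criterion-linked decreases in
#' low-frequency power. In structural volumes the region's gray-matter
#' values are shifted additively by `sum(struct_amp[criteria met])`.
#'
#' @param center Voxel coordinates (1-based) of the sphere centre.
#' @param radius Radius in voxels (>= 1).
#' @param baseline_amp In-band signal amplitude common to all subjects.
#' @param func_amp Numeric length 6, signed per-criterion amplitude added to
#'   the functional in-band signal (order of [criteria_names()]).
#' @param struct_amp Numeric length 6, signed per-criterion additive
#'   gray-matter offset.
#' @return A list of class `effect_region`.
#' @export
effect_region <- function(center, radius, baseline_amp = 1,
                          func_amp = numeric(6), struct_amp = numeric(6)) {
  stopifnot(length(center) == 3, radius >= 1,
            length(func_amp) == 6, length(struct_amp) == 6)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 baseline_amp = as.numeric(baseline_amp),
                 func_amp = as.numeric(func_amp),
                 struct_amp = as.numeric(struct_amp)),
            class = "effect_region")
}

#' Configuration for the synthetic cohort generator
#'
#' Collects everything the simulator needs: the voxel grid, acquisition
#' parameters, criteria model, demographics, planted effects and the
#' mandatory RNG seed. Defaults emulate the structure of a large
#' population-imaging depression cohort: six positively correlated binary
#' criteria whose exact-k group sizes shrink with k, a dominant
#' help-seeking criterion, case groups with a female majority and controls
#' with a male majority, and ages 45-80.
#'
#' Criteria dependence is a single-factor probit model: each subject draws a
#' latent severity z ~ N(0,1) and meets criterion j when
#' `loading * z + sqrt(1 - loading^2) * e_j` exceeds the per-criterion
#' threshold fixed by its marginal prevalence. `criteria_loading = 1` makes
#' the criteria perfectly dependent; 0 makes them independent.
#'
#' @param seed Integer RNG seed (mandatory; all randomness derives from it).
#' @param grid A [volume_grid()]; default 24^3 voxels at 4 mm.
#' @param n_timepoints Functional timepoints (>= 32); default 120.
#' @param tr Repetition time in seconds; default 0.735.
#' @param n_cases,n_controls Cohort sizes; cases always meet >= 1 criterion.
#' @param prevalence Named numeric(6), unconditional marginal prevalence of
#'   each criterion in the case-eligible population (order of
#'   [criteria_names()]), each in (0,1) or exactly 0 to switch a criterion
#'   off.
#' @param criteria_loading Latent-factor loading in [0,1].
#' @param effect_regions List of [effect_region()] objects.
#' @param signal_freq_hz Frequency of the planted in-band oscillation.
#' @param noise_sd SD of the white functional noise.
#' @param age_range,age_case,age_control,education,female_rate_case,
#'   female_rate_control,tiv_male,tiv_female Demographic parameters;
#'   `age_*`, `education` and `tiv_*` are c(mean, sd).
#' @param gm_baseline,gm_noise_sd,gm_smooth_fwhm_mm Structural baseline
#'   level, noise SD and smoothness of the subject gray-matter maps.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_cases = 10, n_controls = 10,
#'                   grid = volume_grid(c(8, 8, 8), 4))
sim_config <- function(seed,
                       grid = volume_grid(c(24, 24, 24), 4),
                       n_timepoints = 120,
                       tr = 0.735,
                       n_cases = 60,
                       n_controls = 60,
                       prevalence = c(helpseek = 0.50, selfrep = 0.126,
                                      antidep = 0.113, smith = 0.085,
                                      icd10 = 0.043, cidisf = 0.096),
                       criteria_loading = 0.55,
                       effect_regions = list(
                         effect_region(center = grid$shape / 2, radius = 4)),
                       signal_freq_hz = 0.045,
                       noise_sd = 1,
                       age_range = c(45, 80),
                       age_case = c(63.9, 7.6),
                       age_control = c(65.0, 7.8),
                       education = c(16.65, 3.8),
                       female_rate_case = 0.617,
                       female_rate_control = 0.447,
                       tiv_male = c(1550, 120),
                       tiv_female = c(1420, 110),
                       gm_baseline = 0.55,
                       gm_noise_sd = 0.08,
                       gm_smooth_fwhm_mm = 8) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(inherits(grid, "volume_grid"),
            n_timepoints >= 32, tr > 0,
            n_cases >= 1, n_controls >= 1,
            length(prevalence) == 6, all(prevalence >= 0),
            all(prevalence < 1),
            criteria_loading >= 0, criteria_loading <= 1,
            signal_freq_hz > 0, signal_freq_hz < 1 / (2 * tr),
            noise_sd > 0, length(age_range) == 2)
  for (r in effect_regions) {
    if (!inherits(r, "effect_region")) stop("effect_regions must be effect_region objects")
    if (r$radius < 1) stop("effect-region radius must be >= 1 voxel")
  }
  names(prevalence) <- .criteria
  structure(list(seed = as.integer(seed), grid = grid,
                 n_timepoints = as.integer(n_timepoints), tr = tr,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 prevalence = prevalence,
                 criteria_loading = criteria_loading,
                 effect_regions = effect_regions,
                 signal_freq_hz = signal_freq_hz,
                 noise_sd = noise_sd,
                 age_range = age_range, age_case = age_case,
                 age_control = age_control, education = education,
                 female_rate_case = female_rate_case,
                 female_rate_control = female_rate_control,
                 tiv_male = tiv_male, tiv_female = tiv_female,
                 gm_baseline = gm_baseline, gm_noise_sd = gm_noise_sd,
                 gm_smooth_fwhm_mm = gm_smooth_fwhm_mm),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_cases, " cases / ", x$n_controls, " controls, grid ",
      paste(x$grid$shape, collapse = "x"), ", ", x$n_timepoints,
      " timepoints @ TR ", x$tr, " s, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# Stable per-subject seed: polynomial hash of the id string folded into the
# global seed, kept below 2^31 so it is a valid R integer seed.
.subject_seed <- function(seed, subject_id) {
  m <- 2147483647
  h <- as.numeric(seed %% m)
  for (code in utf8ToInt(as.character(subject_id)))
    h <- (h * 31 + code) %% m
  as.integer(h)
}

# Evaluate expr with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
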