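#' Draw criteria profiles from the latent-severity model
#'
#' Samples n six-bit criteria profiles under the single-factor probit model
#' described in [sim_config()]. Sampling is unconditional: profiles with
#' k = 0 are returned too (the cohort builder resamples those when it needs
#' cases).
#'
#' @param config A [sim_config()].
#' @param n Number of profiles (> 0).
#' @return Data frame with logical columns `crit_<name>` and integer `k`.
#' @export
sample_criteria <- function(config, n) {
  stopifnot(inherits(config, "sim_config"))
  if (n <= 0) stop("n must be positive")
  lam <- config$criteria_loading
  z <- rnorm(n)
  bits <- matrix(FALSE, n, 6)
  thr <- qnorm(1 - config$prevalence)
  for (j in 1:6) {
    if (config$prevalence[j] <= 0) next  # criterion switched off
    lat <- lam * z + sqrt(1 - lam^2) * rnorm(n)
    bits[, j] <- lat >= thr[j]
  }
  out <- as.data.frame(bits)
  names(out) <- paste0("crit_", .criteria)
  out$k <- as.integer(rowSums(bits))
  out
}

# Demographics for one group ("case" or "control"); truncated-normal age,
# education floored at 7 years, TIV conditional on sex.
.sim_demographics <- function(config, n, group) {
  am <- if (group == "case") config$age_case else config$age_control
  fr <- if (group == "case") config$female_rate_case else config$female_rate_control
  age <- rnorm(n, am[1], am[2])
  bad <- age < config$age_range[1] | age > config$age_range[2]
  while (any(bad)) {
    age[bad] <- rnorm(sum(bad), am[1], am[2])
    bad <- age < config$age_range[1] | age > config$age_range[2]
  }
  sex <- rbinom(n, 1, 1 - fr)  # 0 = female, 1 = male
  edu <- pmax(7, rnorm(n, config$education[1], config$education[2]))
  tiv <- ifelse(sex == 1,
                rnorm(n, config$tiv_male[1], config$tiv_male[2]),
                rnorm(n, config$tiv_female[1], config$tiv_female[2]))
  data.frame(age = round(age, 2), sex = sex,
             education_years = round(edu, 2), tiv_ml = round(tiv, 1))
}

#' Simulate a cohort subject table
#'
#' Builds the case and control rows of a cohort: cases draw criteria
#' profiles from [sample_criteria()] conditioned on meeting at least one
#' criterion (k = 0 draws are resampled); controls have an all-false
#' profile. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `subject_id`, `crit_*`, `k`, `age`,
#'   `sex` (0 female / 1 male), `education_years`, `tiv_ml`, `group`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    prof <- sample_criteria(config, config$n_cases)
    need <- prof$k == 0
    while (any(need)) {
      prof[need, ] <- sample_criteria(config, sum(need))
      need <- prof$k == 0
    }
    cases <- cbind(
      data.frame(subject_id = sprintf("case-%04d", seq_len(config$n_cases))),
      prof, .sim_demographics(config, config$n_cases, "case"),
      data.frame(group = "case"))
    zero <- as.data.frame(matrix(FALSE, config$n_controls, 6))
    names(zero) <- paste0("crit_", .criteria)
    zero$k <- 0L
    ctrls <- cbind(
      data.frame(subject_id = sprintf("ctrl-%04d", seq_len(config$n_controls))),
      zero, .sim_demographics(config, config$n_controls, "control"),
      data.frame(group = "control"))
    rbind(cases, ctrls)
  })
}

# Criteria bits of one subject row as a logical 6-vector.
.row_bits <- function(record) {
  as.logical(unlist(record[paste0("crit_", .criteria)]))
}

#' Simulate the functional and structural volumes of one subject
#'
#' The functional volume is white Gaussian noise (SD `noise_sd`) per voxel
#' and timepoint; inside each planted region all voxels additionally share
#' a sinusoid at `signal_freq_hz` whose amplitude is
#' `baseline_amp + sum(func_amp[criteria met])`, floored at 0. The
#' structural volume is a smooth gray-matter baseline plus additive
#' criterion-linked offsets in the regions. Volumes are bit-reproducible:
#' the RNG stream is seeded from a stable hash of (config seed,
#' subject_id), so cohorts can be generated subject-by-subject in any
#' order.
#'
#' @param record One row of a [simulate_cohort()] table.
#' @param config The same [sim_config()] used for the cohort.
#' @return List with `func` (4D array x,y,z,t) and `struct` (3D array).
#' @export
simulate_subject_volumes <- function(record, config) {
  stopifnot(inherits(config, "sim_config"), nrow(record) == 1)
  g <- config$grid
  if (!all(dim(g$mask) == g$shape)) stop("grid/config mismatch")
  bits <- .row_bits(record)
  V <- prod(g$shape); T <- config$n_timepoints
  .with_seed(.subject_seed(config$seed, record$subject_id), {
    func <- matrix(rnorm(V * T, 0, config$noise_sd), V, T)
    tsec <- (seq_len(T) - 1) * config$tr
    for (r in config$effect_regions) {
      amp <- max(0, r$baseline_amp + sum(r$func_amp[bits]))
      if (amp > 0) {
        phase <- runif(1, 0, 2 * pi)
        s <- amp * sin(2 * pi * config$signal_freq_hz * tsec + phase)
        vox <- which(sphere_mask(g, r$center, r$radius))
        func[vox, ] <- func[vox, ] + rep(s, each = length(vox))
      }
    }
    gm <- smooth_map(array(rnorm(V), g$shape), config$gm_smooth_fwhm_mm, g)
    gm <- config$gm_baseline + config$gm_noise_sd * gm
    for (r in config$effect_regions) {
      off <- sum(r$struct_amp[bits])
      if (off != 0) gm[sphere_mask(g, r$center, r$radius)] <- gm[sphere_mask(g, r$center, r$radius)] + off
    }
    gm <- pmax(gm, 0)
    list(func = array(func, c(g$shape, T)), struct = array(gm, g$shape))
  })
}

#' Generate a cohort on disk
#'
#' Writes the subject table as TSV and, optionally, per-subject NIfTI
#' volumes (`<id>_func.nii.gz` 4D, `<id>_struct.nii.gz` 3D) sharing one
#' affine. Counts per exact-k stratum are reported via `message()`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param write_volumes Write NIfTI volumes as well as the table?
#' @return Invisibly, the subject table.
#' @export
generate_cohort <- function(config, out_dir, write_volumes = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- simulate_cohort(config)
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject_id")
  tab <- subjects
  for (cn in paste0("crit_", .criteria)) tab[[cn]] <- as.integer(tab[[cn]])
  write.table(tab, file.path(out_dir, "subjects.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (write_volumes) {
    vs <- config$grid$voxel_size_mm
    for (i in seq_len(nrow(subjects))) {
      vols <- simulate_subject_volumes(subjects[i, ], config)
      fn <- RNifti::asNifti(vols$func)
      RNifti::pixdim(fn) <- c(vs, config$tr)
      sn <- RNifti::asNifti(vols$struct)
      RNifti::pixdim(sn) <- vs
      id <- subjects$subject_id[i]
      RNifti::writeNifti(fn, file.path(out_dir, paste0(id, "_func.nii.gz")))
      RNifti::writeNifti(sn, file.path(out_dir, paste0(id, "_struct.nii.gz")))
    }
  }
  kc <- table(factor(subjects$k[subjects$group == "case"], levels = 1:6))
  message("cases per exact-k stratum: ",
          paste(sprintf("k=%d:%d", 1:6, kc), collapse = " "))
  invisible(subjects)
}

#' Simulate per-subject measure maps as a voxel-by-subject stack
#'
#' Convenience driver for in-memory experiments: simulates each subject's
#' volumes, computes the requested measure maps and smooths them, without
#' touching disk. Columns follow the row order of `subjects`.
#'
#' @param config A [sim_config()].
#' @param subjects Subject table from [simulate_cohort()].
#' @param modalities Subset of c("falff", "lcor", "gcor", "gmv").
#' @param band A [band_spec()] for fALFF.
#' @param smooth_fwhm_mm FWHM applied to each measure map (0 = none).
#' @param lcor_fwhm_mm Neighbourhood FWHM for LCOR.
#' @return Named list of V x N matrices (V = prod(grid shape)).
#' @export
simulate_measure_stack <- function(config, subjects,
                                   modalities = c("falff", "lcor", "gcor", "gmv"),
                                   band = band_spec(),
                                   smooth_fwhm_mm = 8,
                                   lcor_fwhm_mm = 25) {
  modalities <- match.arg(modalities, several.ok = TRUE)
  g <- config$grid
  V <- prod(g$shape); N <- nrow(subjects)
  out <- lapply(modalities, function(m) matrix(0, V, N))
  names(out) <- modalities
  for (i in seq_len(N)) {
    vols <- simulate_subject_volumes(subjects[i, ], config)
    for (m in modalities) {
      map <- switch(m,
        falff = compute_falff(vols$func, band, config$tr, g),
        lcor  = compute_lcor(vols$func, lcor_fwhm_mm, g),
        gcor  = compute_gcor(vols$func, g),
        gmv   = compute_relative_gmv(vols$struct, subjects$tiv_ml[i], g)$map)
      if (smooth_fwhm_mm > 0) map <- smooth_map(map, smooth_fwhm_mm, g)
      out[[m]][, i] <- as.vector(map)
    }
  }
  out
}
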