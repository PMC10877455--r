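small_cfg <- function(seed = 1, n_cases = 5, n_controls = 5, ...) {
  sim_config(seed = seed, grid = volume_grid(c(6, 6, 6), 4),
             n_timepoints = 40, n_cases = n_cases, n_controls = n_controls,
             effect_regions = list(effect_region(c(3, 3, 3), 2)), ...)
}

test_that("criteria marginals match their configured prevalences", {
  cfg <- sim_config(seed = 42)
  n <- 10000
  prof <- .with_seed_test(99, sample_criteria(cfg, n))
  phat <- colMeans(as.matrix(prof[paste0("crit_", criteria_names())]))
  se <- sqrt(cfg$prevalence * (1 - cfg$prevalence) / n)
  expect_true(all(abs(phat - cfg$prevalence) <= 3 * se))
  expect_identical(prof$k, as.integer(rowSums(prof[1:6])))
})

test_that("maximal loading with equal prevalences gives all-or-none profiles", {
  cfg <- sim_config(seed = 3, prevalence = rep(0.4, 6), criteria_loading = 1)
  prof <- .with_seed_test(7, sample_criteria(cfg, 500))
  k <- prof$k
  expect_true(all(k %in% c(0L, 6L)))
})

test_that("a zero-prevalence criterion never fires", {
  pv <- c(0.5, 0.3, 0, 0.2, 0.1, 0.2)
  cfg <- sim_config(seed = 3, prevalence = pv)
  prof <- .with_seed_test(11, sample_criteria(cfg, 2000))
  expect_false(any(prof$crit_antidep))
  expect_error(sample_criteria(cfg, 0), "positive")
})

test_that("exact-k counts decrease with k under default parameters", {
  cfg <- sim_config(seed = 5)
  prof <- .with_seed_test(13, sample_criteria(cfg, 20000))
  counts <- table(factor(prof$k[prof$k >= 1], levels = 1:6))
  expect_true(all(diff(as.integer(counts)) < 0))
})

test_that("cohort tables partition cases into disjoint exhaustive strata", {
  cfg <- small_cfg(n_cases = 40, n_controls = 20)
  subj <- simulate_cohort(cfg)
  expect_equal(nrow(subj), 60)
  expect_true(all(subj$k[subj$group == "case"] >= 1))
  expect_true(all(subj$k[subj$group == "control"] == 0))
  st <- assign_strata(subj)
  expect_equal(sort(st$subject_id), sort(subj$subject_id[subj$group == "case"]))
  expect_equal(sum(table(st$k)), sum(subj$group == "case"))
  expect_true(all(subj$age >= 45 & subj$age <= 80))
})

test_that("subject volumes are bit-identical for the same seed and id", {
  cfg <- small_cfg()
  subj <- simulate_cohort(cfg)
  v1 <- simulate_subject_volumes(subj[1, ], cfg)
  v2 <- simulate_subject_volumes(subj[1, ], cfg)
  expect_identical(v1$func, v2$func)
  expect_identical(v1$struct, v2$struct)
  v3 <- simulate_subject_volumes(subj[2, ], cfg)
  expect_false(identical(v1$func, v3$func))
})

test_that("controls carry no criterion-linked signal beyond the shared baseline", {
  # with zero baseline, control functional volumes are pure noise: the
  # planted-region mean over 100 seeded controls stays within 3 SE of 0
  reg <- effect_region(c(3, 3, 3), 2, baseline_amp = 0,
                       func_amp = rep(-0.5, 6))
  cfg <- sim_config(seed = 2, grid = volume_grid(c(6, 6, 6), 4),
                    n_timepoints = 40, n_cases = 2, n_controls = 100,
                    effect_regions = list(reg))
  subj <- simulate_cohort(cfg)
  ctrl <- subj[subj$group == "control", ]
  region <- sphere_mask(cfg$grid, c(3, 3, 3), 2)
  nvox <- sum(region) * cfg$n_timepoints
  m <- vapply(seq_len(nrow(ctrl)), function(i) {
    v <- simulate_subject_volumes(ctrl[i, ], cfg)
    mean(array(v$func, c(prod(cfg$grid$shape), cfg$n_timepoints))[region, ])
  }, 0)
  se <- cfg$noise_sd / sqrt(nvox * length(m))
  expect_lt(abs(mean(m)), 3 * se)
})

test_that("zero amplitudes make cases indistinguishable from controls", {
  reg <- effect_region(c(3, 3, 3), 2, baseline_amp = 1, func_amp = numeric(6))
  cfg <- sim_config(seed = 8, grid = volume_grid(c(6, 6, 6), 4),
                    n_timepoints = 40, n_cases = 30, n_controls = 30,
                    effect_regions = list(reg))
  subj <- simulate_cohort(cfg)
  region <- as.vector(sphere_mask(cfg$grid, c(3, 3, 3), 2))
  st <- simulate_measure_stack(cfg, subj, modalities = "falff",
                               smooth_fwhm_mm = 0)
  mm <- colMeans(st$falff[region, ])
  tt <- t.test(mm[subj$group == "case"], mm[subj$group == "control"])
  expect_gt(tt$p.value, 0.001)
})

test_that("generate_cohort writes a reproducible table and readable volumes", {
  cfg <- small_cfg(n_cases = 3, n_controls = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(generate_cohort(cfg, d1, write_volumes = TRUE))
  suppressMessages(generate_cohort(cfg, d2, write_volumes = FALSE))
  t1 <- read.delim(file.path(d1, "subjects.tsv"))
  t2 <- read.delim(file.path(d2, "subjects.tsv"))
  expect_identical(t1, t2)
  expect_identical(unname(tools::md5sum(file.path(d1, "subjects.tsv"))),
                   unname(tools::md5sum(file.path(d2, "subjects.tsv"))))
  v <- RNifti::readNifti(file.path(d1, "case-0001_func.nii.gz"))
  expect_equal(dim(v), c(6, 6, 6, 40))
  ref <- simulate_subject_volumes(t1[1, ], cfg)
  expect_equal(max(abs(as.array(v) - ref$func)), 0, tolerance = 1e-6)
})
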