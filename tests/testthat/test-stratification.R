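test_that("constellation enumeration covers all non-empty subsets in canonical order", {
  c6 <- enumerate_constellations(6)
  expect_equal(nrow(c6), 63)
  expect_equal(nrow(enumerate_constellations(1)), 1)
  c3 <- enumerate_constellations(3)
  expect_equal(nrow(c3), 7)
  # brute-force subset enumeration
  brute <- sort(Reduce(c, lapply(1:3, function(k)
    colSums(2^(combn(0:2, k))))))
  expect_setequal(c3$constellation_id, brute)
  # ordered by (popcount, value); popcount consistent with k
  expect_true(!is.unsorted(c6$k))
  pc <- vapply(c6$constellation_id, function(x) sum(bitwAnd(x, 2^(0:5)) > 0), 0L)
  expect_equal(pc, c6$k)
  expect_true(all(table(c6$k) == choose(6, 1:6)))
  expect_equal(c6$pattern[c6$constellation_id == 63],
               paste(criteria_names(), collapse = "+"))
})

test_that("strata assignment is the exact-k, single-constellation partition", {
  subj <- data.frame(subject_id = c("a", "b", "c"),
                     crit_helpseek = c(FALSE, TRUE, TRUE),
                     crit_selfrep = c(FALSE, TRUE, FALSE),
                     crit_antidep = c(FALSE, TRUE, FALSE),
                     crit_smith = c(FALSE, TRUE, FALSE),
                     crit_icd10 = c(TRUE, TRUE, FALSE),
                     crit_cidisf = c(FALSE, TRUE, FALSE),
                     group = "case")
  st <- assign_strata(subj)
  expect_equal(st$k, c(1L, 6L, 1L))
  expect_equal(st$constellation_id, c(16L, 63L, 1L))

  cfg <- sim_config(seed = 10, n_cases = 100, n_controls = 10,
                    grid = volume_grid(c(4, 4, 4), 4), n_timepoints = 32)
  coh <- simulate_cohort(cfg)
  st2 <- assign_strata(coh)
  expect_equal(nrow(st2), 100)
  expect_equal(sum(table(st2$k)), 100)

  bad <- subj; bad$crit_icd10[1] <- FALSE
  expect_error(assign_strata(bad), "all-false")
})

test_that("matching a pool equal to the cases recovers every case at distance 0", {
  set.seed(1)
  cases <- data.frame(subject_id = paste0("c", 1:20),
                      age = runif(20, 45, 80), sex = rbinom(20, 1, .5),
                      education_years = runif(20, 8, 20))
  pool <- cases; pool$subject_id <- paste0("p", 1:20)
  mm <- match_controls(cases, pool, seed = 4)
  expect_equal(nrow(mm$pairs), 20)
  expect_equal(max(mm$pairs$distance), 0)
  expect_length(mm$unmatched, 0)
  expect_false(anyDuplicated(mm$pairs$control_id) > 0)
})

test_that("matching reports pigeonhole-unmatched cases and is seed-deterministic", {
  cases <- data.frame(subject_id = paste0("c", 1:3), age = c(50, 60, 70),
                      sex = 1, education_years = c(10, 12, 14))
  pool <- data.frame(subject_id = paste0("p", 1:2), age = c(52, 69),
                     sex = 1, education_years = c(10, 14))
  mm <- match_controls(cases, pool, seed = 9)
  expect_equal(nrow(mm$pairs), 2)
  expect_length(mm$unmatched, 1)
  mm2 <- match_controls(cases, pool, seed = 9)
  expect_identical(mm, mm2)
  expect_error(match_controls(cases, pool[0, ]), "empty")
})

test_that("matched pairs are closer in age than the raw pool", {
  res <- vapply(1:10, function(r) {
    set.seed(100 + r)
    cases <- data.frame(subject_id = paste0("c", 1:30),
                        age = rnorm(30, 60, 5), sex = rbinom(30, 1, .5),
                        education_years = rnorm(30, 16, 3))
    pool <- data.frame(subject_id = paste0("p", 1:150),
                       age = rnorm(150, 68, 7), sex = rbinom(150, 1, .5),
                       education_years = rnorm(150, 14, 3))
    mm <- match_controls(cases, pool, seed = r)
    ci <- match(mm$pairs$case_id, cases$subject_id)
    pi <- match(mm$pairs$control_id, pool$subject_id)
    matched_diff <- mean(abs(cases$age[ci] - pool$age[pi]))
    raw_diff <- abs(mean(cases$age) - mean(pool$age))
    matched_diff < raw_diff
  }, TRUE)
  expect_gte(mean(res), 0.9)
  # sexes always identical within a pair
  set.seed(5)
  cases <- data.frame(subject_id = paste0("c", 1:10), age = rnorm(10, 60, 5),
                      sex = rbinom(10, 1, .5), education_years = rnorm(10, 15, 2))
  pool <- data.frame(subject_id = paste0("p", 1:40), age = rnorm(40, 60, 5),
                     sex = rbinom(40, 1, .5), education_years = rnorm(40, 15, 2))
  mm <- match_controls(cases, pool, seed = 2)
  ci <- match(mm$pairs$case_id, cases$subject_id)
  pi <- match(mm$pairs$control_id, pool$subject_id)
  expect_true(all(cases$sex[ci] == pool$sex[pi]))
})
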