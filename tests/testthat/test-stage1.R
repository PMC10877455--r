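test_that("the contrast battery enumerates 48 tests per strategy", {
  sp <- contrast_specs()
  expect_equal(nrow(sp), 96)
  expect_equal(nrow(sp[sp$strategy == "pool", ]), 48)
  expect_equal(nrow(unique(sp[c("modality", "k", "direction")])), 48)
  expect_equal(nrow(contrast_specs("pool", "falff")), 12)
})

test_that("residualization: perfect fit, orthogonality, centering", {
  set.seed(61)
  N <- 40; V <- 30
  cov <- data.frame(age = runif(N, 45, 80), sex = rbinom(N, 1, .5),
                    tiv_ml = rnorm(N, 1500, 100))
  X <- design_matrix(cov)
  # data that is an exact linear function of the design -> zero residuals
  B <- matrix(rnorm(V * ncol(X)), V)
  Y <- B %*% t(X)
  expect_lt(max(abs(residualize(Y, cov))), 1e-8)
  # random data -> residuals orthogonal to every covariate column
  Y2 <- matrix(rnorm(V * N), V, N)
  R <- residualize(Y2, cov)
  expect_lt(max(abs(R %*% X)), 1e-7)
  # intercept-only structure: residuals equal centered data
  R2 <- residualize(Y2, matrix(1, N, 1))
  expect_equal(R2, Y2 - rowMeans(Y2), tolerance = 1e-12)
  # rank-deficient design errors
  Xbad <- cbind(X, X[, 2])
  expect_error(residualize(Y2, Xbad), "rank deficient")
})

test_that("Welch t matches the closed form and the pooled-t identity", {
  w <- welch_t_map(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(w$t, -3.674, tolerance = 5e-4)
  expect_equal(w$df, 4, tolerance = 1e-12)

  # equal n and equal variances: Welch equals the pooled-variance t
  set.seed(71)
  x <- rnorm(12); y <- rnorm(12)
  w2 <- welch_t_map(matrix(c(x, y), nrow = 1), rep(c(TRUE, FALSE), each = 12))
  pooled <- t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(w2$t, unname(pooled), tolerance = 1e-12)

  # symmetric relabeling of identical distributions -> t = 0
  z <- c(1, 2, 3, 1, 2, 3)
  w3 <- welch_t_map(matrix(z, nrow = 1), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(w3$t, 0)
  # zero variance in both groups is flagged, not NaN
  w4 <- welch_t_map(matrix(rep(2, 8), nrow = 1), rep(c(TRUE, FALSE), each = 4))
  expect_equal(w4$t, 0)
  expect_true(w4$zero_variance)
  expect_error(welch_t_map(matrix(1:3, nrow = 1), c(TRUE, FALSE, FALSE)),
               "at least 2")
})

test_that("cluster extraction matches construction and the flood-fill oracle", {
  g <- volume_grid(c(10, 10, 10), 4)
  t0 <- rep(0, prod(g$shape)); df0 <- rep(100, prod(g$shape))
  cl0 <- form_clusters(t0, df0, 0.001, "decrease", g)
  expect_equal(nrow(cl0$table), 0)

  # single 3x3x3 supra-threshold block
  tm <- array(0, g$shape); tm[4:6, 4:6, 4:6] <- -10
  cl1 <- form_clusters(as.vector(tm), df0, 0.001, "decrease", g)
  expect_equal(cl1$table$size, 27)
  expect_equal(nrow(cl1$table), 1)
  # the same map has no increase clusters
  expect_equal(nrow(form_clusters(as.vector(tm), df0, 0.001, "increase", g)$table), 0)

  # random maps against the BFS oracle, all three connectivities
  for (s in 1:3) {
    set.seed(80 + s)
    tr <- array(rnorm(prod(g$shape), 0, 3), g$shape)
    for (conn in c(6, 18, 26)) {
      cl <- form_clusters(as.vector(tr), df0, 0.001, "increase", g,
                          connectivity = conn)
      supra <- array(as.vector(tr) > qt(0.999, 100), g$shape)
      expect_equal(sort(cl$table$size), sort(floodfill_sizes(supra, conn)))
    }
  }
})

test_that("cluster FWE: p floor, reproducibility, and planted-effect recovery", {
  g <- volume_grid(c(12, 12, 12), 4)
  V <- prod(g$shape); N <- 40
  set.seed(91)
  Y <- matrix(0, V, N)
  for (i in 1:N) Y[, i] <- as.vector(smooth_map(array(rnorm(V), g$shape), 8, g))
  sphere <- sphere_mask(g, c(6, 6, 6), 3)
  grp <- rep(c(TRUE, FALSE), each = N / 2)
  # strong planted decrease (d ~ 2 after smoothing dilution)
  Y[as.vector(sphere), grp] <- Y[as.vector(sphere), grp] - 1.0
  res <- cluster_fwe(Y, grp, g, "decrease", n_perm = 199, seed = 5)
  expect_gt(nrow(res$cluster_table), 0)
  expect_true(all(res$cluster_table$p_corrected >= 1 / 200))
  expect_true(all(res$cluster_table$p_corrected <= 1))
  best <- res$cluster_table[which.min(res$cluster_table$p_corrected), ]
  expect_equal(best$p_corrected, 1 / 200)  # larger than every permutation max
  expect_gt(dice(res$mask, sphere), 0.5)
  # every mask voxel is supra-threshold in the right direction
  expect_true(all(res$t_map[res$mask] < 0))

  res2 <- cluster_fwe(Y, grp, g, "decrease", n_perm = 199, seed = 5)
  expect_identical(res2$perm_max, res$perm_max)
  expect_identical(res2$cluster_table, res$cluster_table)

  # shared permutation stream: the two-direction call reproduces the
  # single-direction decrease result
  both <- cluster_fwe(Y, grp, g, c("decrease", "increase"),
                      n_perm = 199, seed = 5)
  expect_identical(both$decrease$cluster_table, res$cluster_table)

  expect_error(cluster_fwe(Y, grp, g, "decrease", n_perm = 100,
                           alpha_cluster = 0.001), "floor")
  expect_error(cluster_fwe(Y, grp, g, "decrease", n_perm = 50), "at least 100")
})

test_that("run_stage1 skips tiny strata and returns direction-consistent masks", {
  g <- volume_grid(c(8, 8, 8), 4)
  cfg <- sim_config(seed = 17, grid = g, n_timepoints = 48,
                    n_cases = 30, n_controls = 30,
                    prevalence = c(.5, .4, .35, .3, .25, .25),
                    criteria_loading = .7,
                    effect_regions = list(effect_region(c(4, 4, 4), 2,
                        func_amp = c(0, 0, -0.6, 0, -0.6, 0))))
  subj <- simulate_cohort(cfg)
  st <- simulate_measure_stack(cfg, subj, "falff", smooth_fwhm_mm = 8)
  s1 <- run_stage1(st, subj, g, "pool", n_perm = 120, seed = 2)
  expect_equal(length(s1$results), 12)  # 6 strata x 2 directions, one modality
  ktab <- table(subj$k[subj$group == "case"])
  for (k in 1:6) {
    key <- sprintf("falff.k%d.decrease", k)
    if (is.na(ktab[as.character(k)]) || ktab[as.character(k)] < 2)
      expect_null(s1$results[[key]])
  }
  for (key in names(s1$masks)) {
    r <- s1$results[[key]]
    if (r$direction == "decrease") expect_true(all(r$t_map[r$mask] < 0))
    else expect_true(all(r$t_map[r$mask] > 0))
  }
})
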