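g5 <- tiny_grid(5)

test_that("fALFF isolates in-band versus out-of-band sinusoids", {
  # 120 timepoints at TR 0.735 s; 0.05 Hz sits inside 0.008-0.09 Hz,
  # 0.30 Hz far outside
  tr <- 0.735; T <- 120
  vin <- sine_volume(g5, T, tr, 0.05, noise_sd = 0.01)
  vout <- sine_volume(g5, T, tr, 0.30, noise_sd = 0.01)
  fin <- compute_falff(vin, band_spec(), tr, g5)
  fout <- compute_falff(vout, band_spec(), tr, g5)
  expect_true(all(fin[g5$mask] >= 0.95))
  expect_true(all(fout[g5$mask] <= 0.05))
  expect_true(all(fin[g5$mask] <= 1))
})

test_that("detrending leaks tone amplitude but not tone power out of band", {
  # rationale for the power-spectrum default: a detrended pure in-band
  # tone keeps ~98% of its power in band but only ~79% of its summed
  # amplitude (the residual ramp spreads across the amplitude spectrum)
  g <- tiny_grid(3)
  tr <- 0.735; T <- 120
  v <- sine_volume(g, T, tr, 4 / (T * tr))
  fp <- compute_falff(v, band_spec(), tr, g, spectrum = "power")
  fa <- compute_falff(v, band_spec(), tr, g, spectrum = "amplitude")
  expect_true(all(fp[g$mask] >= 0.95))
  expect_true(all(fa[g$mask] < 0.85))
  expect_true(all(fa[g$mask] > 0.70))
})

test_that("white-noise fALFF matches the band's share of frequency bins", {
  tr <- 0.735; T <- 120
  nb <- T %/% 2
  f <- seq_len(nb) / (T * tr)
  frac <- mean(f >= 0.008 & f <= 0.09)
  vals <- unlist(lapply(1:20, function(s) {
    set.seed(400 + s)
    v <- array(rnorm(prod(g5$shape) * T), c(g5$shape, T))
    compute_falff(v, band_spec(), tr, g5)[g5$mask]
  }))
  # each voxel's fALFF is a ratio of sums of iid amplitude draws; the mean
  # over 2500 independent voxels pins it down tightly (the small downward
  # bias comes from detrending attenuating the lowest in-band bin)
  expect_lt(abs(mean(vals) - frac), 0.01)
})

test_that("fALFF is invariant to positive rescaling and flags constants", {
  tr <- 0.7; T <- 64
  set.seed(9)
  v <- array(rnorm(prod(g5$shape) * T), c(g5$shape, T))
  f1 <- compute_falff(v, band_spec(), tr, g5)
  f2 <- compute_falff(v * 7.3, band_spec(), tr, g5)
  expect_equal(f1, f2, tolerance = 1e-12)
  vc <- v; vc[1, 1, 1, ] <- 5  # constant after detrending
  expect_warning(fc <- compute_falff(vc, band_spec(), tr, g5), "constant")
  expect_equal(fc[1, 1, 1], 0)
})

test_that("LCOR is 1 for a shared series, ~0 for noise, negative for anticorrelated populations", {
  T <- 200
  shared <- sine_volume(g5, T, 1, 0.1)
  l1 <- compute_lcor(shared + 0, 25, g5)
  expect_equal(max(abs(l1[g5$mask] - 1)), 0, tolerance = 1e-10)

  set.seed(21)
  noise <- array(rnorm(prod(g5$shape) * T), c(g5$shape, T))
  l0 <- compute_lcor(noise, 25, g5)
  expect_lt(abs(mean(l0[g5$mask])), 3 / sqrt(T))

  # interleave +s(t) and -s(t) in a checkerboard: every neighbourhood is
  # dominated by anticorrelated voxels
  s <- sin(2 * pi * 0.1 * seq_len(T))
  V <- prod(g5$shape)
  sgn <- (-1)^(rowSums(which(array(TRUE, g5$shape), arr.ind = TRUE)))
  Y <- outer(sgn, s) + matrix(rnorm(V * T, 0, 0.05), V, T)
  lneg <- compute_lcor(array(Y, c(g5$shape, T)), 25, g5)
  expect_true(all(lneg[g5$mask] < 0))
})

test_that("LCOR agrees with the explicit neighbourhood-loop oracle", {
  g3 <- volume_grid(c(4, 4, 3), c(4, 4, 5))
  T <- 30
  set.seed(31)
  v <- array(rnorm(prod(g3$shape) * T), c(g3$shape, T))
  fast <- compute_lcor(v, 12, g3)
  slow <- lcor_brute(v, 12, g3)
  expect_equal(fast, slow, tolerance = 1e-10)
  g1 <- volume_grid(c(1, 1, 1), 4)
  expect_error(compute_lcor(array(rnorm(T), c(1, 1, 1, T)), 12, g1), "2 in-mask")
})

test_that("GCOR fast path reproduces the O(V^2) brute force", {
  T <- 40
  set.seed(41)
  v <- array(rnorm(prod(g5$shape) * T), c(g5$shape, T))
  expect_equal(compute_gcor(v, g5), gcor_brute(v, g5), tolerance = 1e-10)

  shared <- sine_volume(g5, T, 1, 0.1)
  expect_equal(max(abs(compute_gcor(shared + 0, g5)[g5$mask] - 1)), 0,
               tolerance = 1e-10)
})

test_that("GCOR of a half +s / half -s split hits the closed form -1/(V-1)", {
  g <- volume_grid(c(4, 4, 4), 4)
  V <- prod(g$shape); T <- 50
  s <- sin(2 * pi * 0.07 * seq_len(T))
  sgn <- rep(c(1, -1), each = V / 2)
  v <- array(t(outer(s, sgn)), c(g$shape, T))
  gc <- compute_gcor(v, g)
  expect_equal(unname(gc[g$mask]), rep(-1 / (V - 1), V), tolerance = 1e-10)
})

test_that("GCOR and LCOR are invariant to positive affine voxel rescaling", {
  T <- 60
  set.seed(55)
  v <- array(rnorm(prod(g5$shape) * T), c(g5$shape, T))
  V <- prod(g5$shape)
  a <- runif(V, 0.5, 3); b <- rnorm(V, 0, 10)
  Y <- t(matrix(v, V, T))
  Y2 <- t(t(Y) * a + b)
  v2 <- array(t(Y2), c(g5$shape, T))
  expect_equal(compute_gcor(v, g5), compute_gcor(v2, g5), tolerance = 1e-9)
  expect_equal(compute_lcor(v, 20, g5), compute_lcor(v2, 20, g5),
               tolerance = 1e-9)
})

test_that("relative GMV is total gray matter over TIV", {
  g <- volume_grid(c(10, 10, 10), 10)  # 1 mL voxels
  gm <- array(0.7, dim = g$shape)
  r <- compute_relative_gmv(gm, tiv_ml = 1400, g)
  expect_equal(r$relative_gmv, 0.5)
  expect_equal(compute_relative_gmv(array(0, g$shape), 1000, g)$relative_gmv, 0)
  set.seed(6)
  gm2 <- array(runif(prod(g$shape)), g$shape)
  expect_equal(compute_relative_gmv(gm2, 1234, g)$relative_gmv,
               sum(gm2) * 1 / 1234, tolerance = 1e-12)
  expect_error(compute_relative_gmv(gm2, 0, g), "positive")
})

test_that("smoothing: identity at 0, DC preservation, correct kernel width", {
  g <- volume_grid(c(21, 21, 21), 2)
  set.seed(77)
  m <- array(rnorm(prod(g$shape)), g$shape)
  expect_identical(smooth_map(m, 0, g), m)
  expect_equal(smooth_map(array(3.5, g$shape), 8, g),
               array(3.5, g$shape), tolerance = 1e-12)

  delta <- array(0, g$shape); delta[11, 11, 11] <- 1
  sm <- smooth_map(delta, 8, g)
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  width_vox <- sum(prof >= half)
  expect_lte(abs(width_vox - 8 / 2), 1)  # 8 mm at 2 mm voxels = 4 voxels

  # interior mass is preserved up to the mask-aware boundary renormalisation
  expect_equal(sum(sm), 1, tolerance = 0.01)
})
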