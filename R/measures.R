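#' Frequency band for fALFF
#'
#' @param low,high Band edges in Hz, 0 < low < high. The default
#'   0.008-0.09 Hz is the conventional low-frequency fluctuation band.
#' @return A list of class `band_spec`.
#' @export
band_spec <- function(low = 0.008, high = 0.09) {
  stopifnot(low > 0, high > low)
  structure(list(low = low, high = high), class = "band_spec")
}

# 4D array -> T x V matrix (time in rows), V = all grid voxels.
.ts_matrix <- function(ts_volume, grid) {
  d <- dim(ts_volume)
  if (length(d) != 4 || !all(d[1:3] == grid$shape))
    stop("time-series volume does not match the grid")
  t(matrix(ts_volume, prod(d[1:3]), d[4]))
}

# TRUE for columns with zero variance.
.zero_var_cols <- function(Y) {
  mu <- colMeans(Y)
  colSums((Y - rep(mu, each = nrow(Y)))^2) == 0
}

# Columns standardised to mean 0, unit L2 norm; constant columns -> 0.
# Returns list(z, nonconst).
.standardise_ts <- function(Y) {
  Y <- sweep(Y, 2, colMeans(Y))
  nrm <- sqrt(colSums(Y^2))
  nonconst <- nrm > 0
  Y[, nonconst] <- sweep(Y[, nonconst, drop = FALSE], 2, nrm[nonconst], "/")
  Y[, !nonconst] <- 0
  list(z = Y, nonconst = nonconst)
}

#' Voxel-wise fractional amplitude of low-frequency fluctuations
#'
#' For each in-mask voxel, removes the mean and linear trend from the time
#' series, takes the FFT spectrum, and returns the ratio of the summed
#' spectral content over frequency bins whose centres fall inside
#' `[band$low, band$high]` (both edges inclusive) to the sum over all
#' positive-frequency bins. Values lie in [0, 1]. Constant series give 0
#' with a warning.
#'
#' The default uses the power spectrum (squared FFT modulus): after linear
#' detrending, a residual ramp component leaks broadly across the
#' amplitude spectrum but negligibly in power, so the power ratio cleanly
#' separates in-band from out-of-band signal on unwindowed series. The
#' classical amplitude convention is available via `spectrum`.
#'
#' @param ts_volume 4D array (x, y, z, t).
#' @param band A [band_spec()].
#' @param tr Repetition time in seconds.
#' @param grid A [volume_grid()].
#' @param spectrum "power" (default) or "amplitude".
#' @return 3D array; voxels outside the mask are NA.
#' @export
compute_falff <- function(ts_volume, band = band_spec(), tr, grid,
                          spectrum = c("power", "amplitude")) {
  spectrum <- match.arg(spectrum)
  stopifnot(inherits(band, "band_spec"), tr > 0)
  T <- dim(ts_volume)[4]
  if (T < 32) stop("need at least 32 timepoints")
  if (band$high >= 1 / (2 * tr)) stop("band extends beyond Nyquist")
  Y <- .ts_matrix(ts_volume, grid)[, as.vector(grid$mask), drop = FALSE]
  const <- .zero_var_cols(Y)
  X <- cbind(1, seq_len(T))
  Y <- Y - X %*% solve(crossprod(X), crossprod(X, Y))  # detrend
  nb <- T %/% 2
  A <- Mod(mvfft(Y))[2:(nb + 1), , drop = FALSE]
  if (spectrum == "power") A <- A * A
  f <- seq_len(nb) / (T * tr)
  inband <- f >= band$low & f <= band$high
  tot <- colSums(A)
  val <- colSums(A[inband, , drop = FALSE]) / pmax(tot, .Machine$double.xmin)
  val[const | tot == 0] <- 0
  if (any(const | tot == 0)) warning("constant time series inside mask; fALFF set to 0")
  out <- array(NA_real_, grid$shape)
  out[grid$mask] <- val
  out
}

#' Voxel-wise local correlation (LCOR)
#'
#' Gaussian-weighted average Pearson correlation between each in-mask
#' voxel's time series and those of its neighbours. Weights come from a
#' spatial Gaussian of the given FWHM (truncated at 4 sigma) restricted to
#' the analysis mask, with the self-weight excluded. Correlations with
#' constant neighbours count as 0. Values lie in [-1, 1].
#'
#' @param ts_volume 4D array (x, y, z, t).
#' @param kernel_fwhm_mm Neighbourhood FWHM in mm (> 0). The default 25 mm
#'   is a package choice, exposed because no single community value exists.
#' @param grid A [volume_grid()].
#' @return 3D array; voxels outside the mask are NA.
#' @export
compute_lcor <- function(ts_volume, kernel_fwhm_mm = 25, grid) {
  stopifnot(kernel_fwhm_mm > 0)
  if (sum(grid$mask) < 2) stop("LCOR needs at least 2 in-mask voxels")
  Y <- .ts_matrix(ts_volume, grid)
  Y[, !as.vector(grid$mask)] <- 0
  st <- .standardise_ts(Y)
  z <- st$z
  T <- nrow(z)
  k <- .grid_kernels(grid, kernel_fwhm_mm)
  num <- array(0, grid$shape)
  for (t in seq_len(T)) {
    zt <- array(z[t, ], grid$shape)
    num <- num + zt * .conv3d(zt, k[[1]], k[[2]], k[[3]])
  }
  W <- .conv3d(grid$mask + 0, k[[1]], k[[2]], k[[3]])
  self <- array(0, grid$shape)
  self[grid$mask] <- as.numeric(st$nonconst[as.vector(grid$mask)])
  den <- W - 1  # centre weight of the truncated separable kernel is exactly 1
  if (any(den[grid$mask] <= 0)) stop("a mask voxel has no neighbours within the kernel")
  out <- array(NA_real_, grid$shape)
  out[grid$mask] <- (num[grid$mask] - self[grid$mask]) / den[grid$mask]
  out
}

#' Voxel-wise global correlation (GCOR)
#'
#' Mean Pearson correlation between each in-mask voxel's time series and
#' those of all other in-mask voxels. Computed in O(V x T) by summing
#' standardised series: with unit-norm series z_v,
#' gcor(v) = (z_v . sum_u z_u - 1) / (V - 1). An O(V^2) brute-force
#' equivalent is kept in the test suite as the oracle. Correlations with
#' constant voxels count as 0 (with a warning).
#'
#' @param ts_volume 4D array (x, y, z, t).
#' @param grid A [volume_grid()].
#' @return 3D array; voxels outside the mask are NA.
#' @export
compute_gcor <- function(ts_volume, grid) {
  Vm <- sum(grid$mask)
  if (Vm < 2) stop("GCOR needs at least 2 in-mask voxels")
  Y <- .ts_matrix(ts_volume, grid)[, as.vector(grid$mask), drop = FALSE]
  st <- .standardise_ts(Y)
  if (!all(st$nonconst)) warning("constant voxel series; correlations with it set to 0")
  s <- rowSums(st$z)
  dot <- as.vector(crossprod(st$z, s))        # z_v . sum_u z_u
  val <- (dot - as.numeric(st$nonconst)) / (Vm - 1)
  out <- array(NA_real_, grid$shape)
  out[grid$mask] <- val
  out
}

#' Relative gray-matter volume and voxel-wise GMV map
#'
#' The scalar relative GMV is total gray-matter volume (voxel volume times
#' the sum of in-mask gray-matter values) divided by total intracranial
#' volume. The voxel-wise map is passed through (masked) for smoothing and
#' voxel-wise analysis.
#'
#' @param gm_volume 3D gray-matter array (tissue fraction per voxel).
#' @param tiv_ml Total intracranial volume in mL (> 0).
#' @param grid A [volume_grid()].
#' @return List with `relative_gmv` (scalar) and `map` (3D array).
#' @export
compute_relative_gmv <- function(gm_volume, tiv_ml, grid) {
  if (tiv_ml <= 0) stop("tiv must be positive")
  gm_volume <- array(as.numeric(gm_volume), grid$shape)
  vox_ml <- prod(grid$voxel_size_mm) / 1000
  total <- sum(gm_volume[grid$mask]) * vox_ml
  map <- gm_volume
  map[!grid$mask] <- NA_real_
  list(relative_gmv = total / tiv_ml, map = map)
}
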