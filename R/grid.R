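#' Define the shared voxel grid for an analysis
#'
#' All per-subject volumes in a cohort live on one grid: a 3D array shape, a
#' physical voxel size in mm, and a binary analysis mask restricting every
#' voxel-wise computation.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_size_mm Numeric voxel edge length(s) in mm; recycled to 3.
#' @param mask Optional logical 3D array of the same shape; default all TRUE.
#' @return An object of class `volume_grid`.
#' @export
#' @examples
#' g <- volume_grid(c(16, 16, 16), 4)
#' sum(g$mask)
volume_grid <- function(shape, voxel_size_mm = 4, mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3)
  stopifnot(all(voxel_size_mm > 0))
  if (is.null(mask)) {
    mask <- array(TRUE, dim = shape)
  } else {
    mask <- array(as.logical(mask), dim = shape)
    if (!any(mask)) stop("analysis mask is empty")
  }
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm, mask = mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$shape, collapse = " x "),
      "voxels @", paste(x$voxel_size_mm, collapse = "/"), "mm;",
      sum(x$mask), "in mask\n")
  invisible(x)
}

#' Spherical region of interest on a grid
#'
#' @param grid A `volume_grid`.
#' @param center Voxel coordinates (1-based) of the sphere centre.
#' @param radius Radius in voxels.
#' @return Logical 3D array.
#' @export
sphere_mask <- function(grid, center, radius) {
  stopifnot(inherits(grid, "volume_grid"), length(center) == 3, radius >= 1)
  d <- grid$shape
  dx <- (seq_len(d[1]) - center[1])^2
  dy <- (seq_len(d[2]) - center[2])^2
  dz <- (seq_len(d[3]) - center[3])^2
  r2 <- outer(outer(dx, dy, "+"), dz, "+")
  array(r2 <= radius^2, dim = d)
}

# 1D truncated Gaussian convolution matrix (n x n), unnormalised weights:
# w(d) = exp(-d^2 / (2 sigma^2)) for |d| <= radius, in voxel units.
.gauss_band <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  d <- outer(seq_len(n), seq_len(n), "-")
  w <- exp(-d^2 / (2 * sigma_vox^2))
  w[abs(d) > r] <- 0
  w
}

# Separable 3D convolution with per-axis banded Gaussian matrices.
# Returns the *unnormalised* weighted sum; callers divide by the convolved
# mask when a weighted average is wanted.
.conv3d <- function(arr, kx, ky, kz) {
  d <- dim(arr)
  m <- kx %*% matrix(arr, d[1], d[2] * d[3])            # axis 1
  arr <- array(m, d)
  arr <- aperm(arr, c(2, 1, 3))
  m <- ky %*% matrix(arr, d[2], d[1] * d[3])            # axis 2
  arr <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  arr <- aperm(arr, c(3, 2, 1))
  m <- kz %*% matrix(arr, d[3], d[2] * d[1])            # axis 3
  aperm(array(m, c(d[3], d[2], d[1])), c(3, 2, 1))
}

.fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Gaussian kernels per axis for a physical FWHM on a given grid.
.grid_kernels <- function(grid, fwhm_mm) {
  sig <- .fwhm_to_sigma(fwhm_mm) / grid$voxel_size_mm
  list(.gauss_band(grid$shape[1], sig[1]),
       .gauss_band(grid$shape[2], sig[2]),
       .gauss_band(grid$shape[3], sig[3]))
}

#' Mask-aware Gaussian smoothing of a 3D map
#'
#' Smooths with a Gaussian kernel of the given full-width at half-maximum,
#' specified in mm and converted per axis to voxel units
#' (sigma = FWHM / (2 sqrt(2 ln 2))). Values outside the analysis mask are
#' ignored and the kernel is renormalised over in-mask voxels, so a constant
#' in-mask image is reproduced exactly and edges are not attenuated.
#' `fwhm_mm = 0` is the identity.
#'
#' @param map Numeric 3D array on `grid`.
#' @param fwhm_mm Kernel FWHM in mm (>= 0).
#' @param grid A `volume_grid`.
#' @return Smoothed 3D array; voxels outside the mask are set to 0.
#' @export
smooth_map <- function(map, fwhm_mm, grid) {
  stopifnot(inherits(grid, "volume_grid"), fwhm_mm >= 0)
  map <- array(as.numeric(map), dim = grid$shape)
  map[!grid$mask] <- 0  # out-of-mask values (incl. NA) never contribute
  if (fwhm_mm == 0) return(map)
  k <- .grid_kernels(grid, fwhm_mm)
  m <- grid$mask + 0
  num <- .conv3d(map, k[[1]], k[[2]], k[[3]])
  den <- .conv3d(m, k[[1]], k[[2]], k[[3]])
  out <- array(0, dim = grid$shape)
  out[grid$mask] <- num[grid$mask] / den[grid$mask]
  out
}
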