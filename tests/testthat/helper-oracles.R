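# Independent brute-force oracles, deliberately naive implementations.

# Mean correlation of each in-mask voxel with all other in-mask voxels.
gcor_brute <- function(ts_volume, grid) {
  d <- dim(ts_volume)
  Y <- t(matrix(ts_volume, prod(d[1:3]), d[4]))[, as.vector(grid$mask), drop = FALSE]
  C <- cor(Y)
  V <- ncol(Y)
  out <- array(NA_real_, grid$shape)
  out[grid$mask] <- (colSums(C) - 1) / (V - 1)
  out
}

# Gaussian-weighted mean neighbour correlation, plain loops.
lcor_brute <- function(ts_volume, fwhm_mm, grid) {
  d <- grid$shape
  Y <- t(matrix(ts_volume, prod(d), dim(ts_volume)[4]))
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size_mm
  rax <- pmax(1L, ceiling(4 * sig))  # same per-axis truncation as the kernel
  r <- max(rax)
  idx <- which(grid$mask, arr.ind = TRUE)
  out <- array(NA_real_, d)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    num <- 0; den <- 0
    for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- p + c(dx, dy, dz)
      if (any(q < 1) || any(q > d)) next
      if (!grid$mask[q[1], q[2], q[3]]) next
      w <- exp(-(dx^2 / (2 * sig[1]^2) + dy^2 / (2 * sig[2]^2) +
                   dz^2 / (2 * sig[3]^2)))
      if (abs(dx) > rax[1] || abs(dy) > rax[2] || abs(dz) > rax[3])
        w <- 0  # match the truncated kernel
      a <- Y[, (p[1] - 1) + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1)) + 1]
      b <- Y[, (q[1] - 1) + d[1] * ((q[2] - 1) + d[2] * (q[3] - 1)) + 1]
      cc <- if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
      num <- num + w * cc
      den <- den + w
    }
    out[p[1], p[2], p[3]] <- num / den
  }
  out
}

# Connected components by breadth-first search.
floodfill_sizes <- function(supra, connectivity = 26) {
  d <- dim(supra)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nz <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  off <- off[nz > 0 & nz <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  seen <- array(FALSE, d)
  sizes <- integer()
  coords <- which(supra, arr.ind = TRUE)
  for (i in seq_len(nrow(coords))) {
    p0 <- coords[i, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    queue <- list(p0); seen[p0[1], p0[2], p0[3]] <- TRUE
    sz <- 0L
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      sz <- sz + 1L
      for (j in seq_len(nrow(off))) {
        q <- p + as.integer(off[j, ])
        if (any(q < 1) || any(q > d)) next
        if (supra[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

# Dice overlap of two logical arrays.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# A small default test grid.
tiny_grid <- function(n = 5, vox = 4) volume_grid(rep(n, 3), vox)

# Sinusoidal 4D volume: every voxel carries amp * sin(2 pi f t) plus noise.
sine_volume <- function(grid, T, tr, freq, amp = 1, noise_sd = 0, seed = 1) {
  set.seed(seed)
  V <- prod(grid$shape)
  s <- amp * sin(2 * pi * freq * (seq_len(T) - 1) * tr)
  Y <- matrix(rep(s, each = V), V, T)
  if (noise_sd > 0) Y <- Y + matrix(rnorm(V * T, 0, noise_sd), V, T)
  array(Y, c(grid$shape, T))
}

# Run expr under a local seed without disturbing the session RNG state.
.with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
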