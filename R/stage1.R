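#' Enumerate the stage-1 contrast design
#'
#' Two directional tests (increase, decrease) per imaging modality, for
#' each of the 6 exact-k strata and 4 modalities: 48 contrasts per control
#' strategy.
#'
#' @param strategies Character vector of control strategies.
#' @param modalities Imaging modalities.
#' @return Data frame with one row per contrast.
#' @export
contrast_specs <- function(strategies = c("pool", "matched"),
                           modalities = c("falff", "lcor", "gcor", "gmv")) {
  out <- expand.grid(direction = c("decrease", "increase"),
                     k = 1:6, modality = modalities,
                     strategy = strategies,
                     stringsAsFactors = FALSE)
  out[c("strategy", "modality", "k", "direction")]
}

#' Nuisance design matrix for stage-1 adjustment
#'
#' Columns: intercept, age, age squared, sex, total intracranial volume.
#' The group indicator is deliberately excluded; group structure must
#' survive residualization. Covariate columns that are constant in the
#' current subsample (e.g. sex within a single-sex matched stratum) are
#' absorbed by the intercept and dropped.
#'
#' @param covariates Data frame with `age`, `sex`, `tiv_ml`.
#' @return Numeric matrix with one row per subject.
#' @export
design_matrix <- function(covariates) {
  X <- cbind(intercept = 1, age = covariates$age, age2 = covariates$age^2,
             sex = covariates$sex, tiv = covariates$tiv_ml)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v) var(v) > 0))
  X <- X[, keep, drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("nuisance design matrix is rank deficient")
  X
}

#' Residualize a measure stack against nuisance covariates
#'
#' Per voxel, ordinary least-squares residuals from regressing the measure
#' on the nuisance design fitted over the combined sample (cases and
#' controls together).
#'
#' @param Y Numeric V x N matrix (voxels by subjects).
#' @param covariates Data frame as for [design_matrix()], N rows, or a
#'   prebuilt numeric design matrix.
#' @return V x N residual matrix.
#' @export
residualize <- function(Y, covariates) {
  X <- if (is.matrix(covariates)) covariates else design_matrix(covariates)
  stopifnot(nrow(X) == ncol(Y))
  if (qr(X)$rank < ncol(X)) stop("nuisance design matrix is rank deficient")
  Q <- qr.Q(qr(X))
  Y - (Y %*% Q) %*% t(Q)
}

# Welch statistics for a V x N data matrix against 0/1 indicator columns
# W (N x P), every column containing the same group-1 size n1.
# Returns V x P matrices t and df. Sign: group1 minus group0.
.welch_stats <- function(Y, W, n1 = sum(W[, 1])) {
  N <- ncol(Y)
  n2 <- N - n1
  sy <- rowSums(Y); sy2 <- rowSums(Y^2)
  S1 <- Y %*% W; Q1 <- (Y * Y) %*% W
  m1 <- S1 / n1
  m2 <- (sy - S1) / n2            # sy recycles down columns
  v1 <- pmax(Q1 - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax((sy2 - Q1) - n2 * m2^2, 0) / (n2 - 1)
  a <- v1 / n1; b <- v2 / n2
  se2 <- a + b
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  zero <- se2 == 0
  if (any(zero)) {
    tt[zero] <- 0
    df[zero] <- n1 + n2 - 2
  }
  list(t = tt, df = df, zero_variance = zero)
}

#' Voxel-wise Welch two-sample t map
#'
#' Welch t statistic (unequal variances) with Satterthwaite degrees of
#' freedom per voxel. Sign convention: case minus control, so negative t
#' means the measure is reduced in the depression group. Voxels with zero
#' variance in both groups get t = 0 and are flagged.
#'
#' @param Y V x N matrix (typically residualized), columns = subjects.
#' @param group Logical or 0/1 vector, TRUE/1 = case.
#' @return List with vectors `t`, `df` and logical `zero_variance`.
#' @export
welch_t_map <- function(Y, group) {
  g <- as.numeric(as.logical(group))
  if (sum(g) < 2 || sum(1 - g) < 2) stop("both groups need at least 2 subjects")
  st <- .welch_stats(Y, matrix(g, ncol = 1))
  list(t = as.vector(st$t), df = as.vector(st$df),
       zero_variance = as.vector(st$zero_variance))
}

# One-sided supra-threshold indicator at voxel p < p_voxel for a direction,
# with per-element Satterthwaite df. qt() is evaluated only on candidates
# passing the loosest critical value, which keeps the permutation loop cheap.
.supra_threshold <- function(tt, df, p_voxel, direction) {
  s <- if (direction == "decrease") -tt else tt
  tcrit_loose <- qt(1 - p_voxel, max(df))
  cand <- which(s > tcrit_loose)
  out <- array(FALSE, dim = dim(s))
  if (length(cand))
    out[cand] <- s[cand] > qt(1 - p_voxel, df[cand])
  out
}

#' Extract supra-threshold clusters from a t map
#'
#' Thresholds the map at one-sided voxel p < `p_voxel` in the requested
#' direction and groups surviving in-mask voxels into connected components
#' (26-connectivity by default).
#'
#' @param t_map,df_map Numeric vectors/arrays over all grid voxels.
#' @param p_voxel Cluster-forming voxel threshold (one-sided).
#' @param direction "decrease" (t < 0) or "increase" (t > 0).
#' @param grid A [volume_grid()].
#' @param connectivity 6, 18 or 26.
#' @return List with `table` (cluster_id, size, peak |t|, peak voxel index)
#'   and `labels` (integer 3D array, 0 = background).
#' @export
form_clusters <- function(t_map, df_map, p_voxel = 0.001,
                          direction = c("decrease", "increase"),
                          grid, connectivity = 26) {
  direction <- match.arg(direction)
  stopifnot(p_voxel > 0, p_voxel < 1)
  tt <- as.vector(t_map); df <- as.vector(df_map)
  supra <- as.vector(.supra_threshold(matrix(tt), matrix(df), p_voxel, direction))
  supra[!as.vector(grid$mask)] <- FALSE
  labels <- .cc_label_3d(supra, grid$shape, as.integer(connectivity))
  sizes <- attr(labels, "sizes")
  n <- attr(labels, "n_clusters")
  tab <- data.frame(cluster_id = integer(), size = integer(),
                    max_abs_t = numeric(), peak_index = integer())
  if (n > 0) {
    lv <- as.vector(labels)
    peak <- vapply(seq_len(n), function(i) {
      vox <- which(lv == i)
      vox[which.max(abs(tt[vox]))]
    }, 0L)
    tab <- data.frame(cluster_id = seq_len(n), size = sizes,
                      max_abs_t = abs(tt[peak]), peak_index = peak)
  }
  list(table = tab, labels = labels)
}

#' Cluster-level family-wise error control by maximum-extent permutation
#'
#' Builds the null distribution of the maximum cluster extent by permuting
#' group labels over the (already residualized) data, re-computing the
#' Welch map and re-applying the cluster-forming rule — a Freedman-Lane
#' style scheme in which the nuisance fit is held fixed. The corrected
#' p-value of an observed cluster of size s is
#' (1 + #\{permutation max >= s\}) / (1 + n_perm); the significance mask is
#' the union of clusters with corrected p < `alpha_cluster`.
#'
#' @param Y Residualized V x N stack (all grid voxels; out-of-mask rows
#'   are ignored).
#' @param group Logical/0-1 vector, TRUE = case.
#' @param grid A [volume_grid()].
#' @param direction "decrease", "increase", or both. When both are given
#'   the directional tests share one permutation stream (the two
#'   directional contrasts of one model) and a named list of results is
#'   returned.
#' @param p_voxel Cluster-forming threshold (one-sided voxel p).
#' @param alpha_cluster Cluster-level FWE threshold.
#' @param n_perm Number of permutations (>= 100; the achievable p floor
#'   1/(n_perm+1) must not exceed `alpha_cluster`).
#' @param seed Integer seed for the permutation stream.
#' @param connectivity 6, 18 or 26.
#' @return For a single direction, a list (`stat_result`): `t_map`,
#'   `df_map` (3D arrays), `cluster_table` with corrected p per cluster,
#'   logical `mask`, `perm_max` (null max extents), plus the call
#'   parameters. For two directions, a named list of two `stat_result`s.
#' @export
cluster_fwe <- function(Y, group, grid, direction = c("decrease", "increase"),
                        p_voxel = 0.001, alpha_cluster = 0.05,
                        n_perm = 1000, seed = 1, connectivity = 26) {
  direction <- match.arg(direction, several.ok = TRUE)
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (1 / (n_perm + 1) > alpha_cluster)
    stop("n_perm too small for alpha_cluster: p floor 1/(n_perm+1) exceeds it")
  g <- as.numeric(as.logical(group))
  inmask <- as.vector(grid$mask)
  Ym <- Y[inmask, , drop = FALSE]
  obs <- welch_t_map(Ym, g)
  t_full <- rep(0, prod(grid$shape)); df_full <- rep(Inf, prod(grid$shape))
  t_full[inmask] <- obs$t; df_full[inmask] <- obs$df
  cl <- lapply(direction, function(d)
    form_clusters(t_full, df_full, p_voxel, d, grid, connectivity))
  names(cl) <- direction

  n1 <- sum(g); N <- length(g)
  perm_max <- matrix(0L, n_perm, length(direction),
                     dimnames = list(NULL, direction))
  chunk <- max(1L, min(n_perm, floor(4e6 / nrow(Ym))))
  done <- 0L
  Ym2 <- Ym * Ym
  sy <- rowSums(Ym); sy2 <- rowSums(Ym2)
  .with_seed(seed, {
    while (done < n_perm) {
      p <- min(chunk, n_perm - done)
      W <- vapply(seq_len(p), function(i) sample(g), numeric(N))
      supra <- .welch_supra(Ym %*% W, Ym2 %*% W, sy, sy2,
                            n1, N - n1, p_voxel)
      for (d in direction) {
        full <- matrix(FALSE, prod(grid$shape), p)
        full[inmask, ] <- supra[[d]]
        perm_max[done + seq_len(p), d] <-
          .cc_max_extent(full, grid$shape, as.integer(connectivity))
      }
      done <- done + p
    }
  })

  out <- lapply(direction, function(d) {
    tab <- cl[[d]]$table
    pm <- perm_max[, d]
    tab$p_corrected <- if (nrow(tab))
      vapply(tab$size, function(s) (1 + sum(pm >= s)) / (1 + n_perm), 0)
    else numeric()
    mask <- array(FALSE, grid$shape)
    sig <- tab$cluster_id[tab$p_corrected < alpha_cluster]
    if (length(sig)) mask[cl[[d]]$labels %in% sig] <- TRUE
    structure(list(t_map = array(t_full, grid$shape),
                   df_map = array(df_full, grid$shape),
                   cluster_table = tab, mask = mask, labels = cl[[d]]$labels,
                   perm_max = pm, direction = d,
                   p_voxel = p_voxel, alpha_cluster = alpha_cluster,
                   n_perm = n_perm, seed = seed),
              class = "stat_result")
  })
  names(out) <- direction
  if (length(direction) == 1) out[[1]] else out
}

#' Run the full stage-1 contrast battery
#'
#' For every modality, exact-k stratum and direction, residualizes the
#' measure stack of (stratum cases + controls) on the nuisance design and
#' applies [cluster_fwe()]. Strata with fewer than `min_cases` cases are
#' skipped (mask absent). With the "matched" strategy each stratum is
#' compared against its 1:1 matched controls; with "pool", against all
#' controls.
#'
#' @param stacks Named list of V x N measure matrices (columns follow
#'   `subjects` rows).
#' @param subjects Subject table; `strata` from [assign_strata()].
#' @param grid A [volume_grid()].
#' @param strategy "pool" or "matched".
#' @param n_perm,p_voxel,alpha_cluster,connectivity Passed to [cluster_fwe()].
#' @param seed Base seed; each contrast derives its own stream.
#' @param min_cases Minimum stratum size to attempt a test.
#' @param matching_seed Seed for [match_controls()] under "matched".
#' @return List with `results` (named list of `stat_result` or NULL, names
#'   `<modality>.k<k>.<direction>`) and `masks` (same names, logical arrays
#'   for non-empty significance masks only).
#' @export
run_stage1 <- function(stacks, subjects, grid, strategy = c("pool", "matched"),
                       n_perm = 1000, p_voxel = 0.001, alpha_cluster = 0.05,
                       connectivity = 26, seed = 1, min_cases = 2,
                       matching_seed = 1) {
  strategy <- match.arg(strategy)
  strata <- assign_strata(subjects)
  ctrl_idx_all <- which(subjects$group == "control")
  specs <- contrast_specs(strategy, names(stacks))
  results <- list(); masks <- list()
  cell <- 0L
  for (mod in names(stacks)) {
    for (k in 1:6) {
      cell <- cell + 1L
      keys <- sprintf("%s.k%d.%s", mod, k, c("decrease", "increase"))
      ids <- strata$subject_id[strata$k == k]
      case_idx <- match(ids, subjects$subject_id)
      ctrl_idx <- ctrl_idx_all
      if (strategy == "matched" && length(case_idx) >= min_cases) {
        mm <- match_controls(subjects[case_idx, ], subjects[ctrl_idx_all, ],
                             seed = matching_seed + k)
        ctrl_idx <- match(mm$pairs$control_id, subjects$subject_id)
        case_idx <- match(mm$pairs$case_id, subjects$subject_id)
      }
      if (length(case_idx) < min_cases || length(ctrl_idx) < 2) {
        results[keys[1]] <- list(NULL); results[keys[2]] <- list(NULL)
        next
      }
      sel <- c(case_idx, ctrl_idx)
      if (length(sel) < 8) {  # too few residual df for the nuisance design
        results[keys[1]] <- list(NULL); results[keys[2]] <- list(NULL)
        next
      }
      Y <- residualize(stacks[[mod]][, sel, drop = FALSE],
                       subjects[sel, , drop = FALSE])
      res <- cluster_fwe(Y, rep(c(TRUE, FALSE), c(length(case_idx), length(ctrl_idx))),
                         grid, c("decrease", "increase"), p_voxel,
                         alpha_cluster, n_perm,
                         seed = seed + 997L * cell, connectivity = connectivity)
      for (d in c("decrease", "increase")) {
        key <- sprintf("%s.k%d.%s", mod, k, d)
        results[[key]] <- res[[d]]
        if (any(res[[d]]$mask)) masks[[key]] <- res[[d]]$mask
      }
    }
  }
  list(results = results, masks = masks, specs = specs, strategy = strategy)
}
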