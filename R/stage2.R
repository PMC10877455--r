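#' Mean value of a map inside a binary mask
#'
#' @param measure_map 3D array (or vector over all grid voxels).
#' @param mask Logical array of the same length; must be non-empty.
#' @return Scalar mean over mask voxels.
#' @export
mask_mean <- function(measure_map, mask) {
  mask <- as.logical(mask)
  if (!any(mask)) stop("empty mask")
  if (length(measure_map) != length(mask)) stop("mask not aligned to map")
  mean(measure_map[mask])
}

#' Per-subject mask means for a set of masks
#'
#' @param stack V x N measure matrix.
#' @param masks Named list of logical arrays.
#' @return N x length(masks) matrix of means, columns named after masks.
#' @export
mask_means <- function(stack, masks) {
  out <- vapply(masks, function(m) {
    m <- as.logical(m)
    if (!any(m)) stop("empty mask")
    colMeans(stack[m, , drop = FALSE])
  }, numeric(ncol(stack)))
  matrix(out, ncol = length(masks),
         dimnames = list(NULL, names(masks)))
}

#' Cohen's d with confidence interval
#'
#' Standardized mean difference (case minus control) over the pooled SD:
#' d = (m1 - m2) / s_p with
#' s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2).
#' The 95% CI is a seeded percentile bootstrap over subjects by default;
#' an analytic noncentral-t interval is available via `ci_method`.
#'
#' @param case_values,control_values Numeric vectors (length >= 2 each).
#' @param ci Compute a confidence interval?
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap stream.
#' @param conf Confidence level.
#' @param ci_method "bootstrap" (percentile) or "noncentral_t".
#' @return List with `d`, `n_case`, `n_control`, and `ci_low`/`ci_high`.
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(4, 5, 6), ci = FALSE)$d  # -3
cohens_d <- function(case_values, control_values, ci = TRUE, n_boot = 1000,
                     seed = 1, conf = 0.95, ci_method = c("bootstrap", "noncentral_t")) {
  ci_method <- match.arg(ci_method)
  x <- case_values; y <- control_values
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled SD")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  out <- list(d = d, n_case = n1, n_control = n2,
              ci_low = NA_real_, ci_high = NA_real_)
  if (!ci) return(out)
  a <- (1 - conf) / 2
  if (ci_method == "bootstrap") {
    bd <- .with_seed(seed, vapply(seq_len(n_boot), function(i) {
      xb <- x[sample.int(n1, replace = TRUE)]
      yb <- y[sample.int(n2, replace = TRUE)]
      s2 <- ((n1 - 1) * var(xb) + (n2 - 1) * var(yb)) / (n1 + n2 - 2)
      if (s2 == 0) return(NA_real_)
      (mean(xb) - mean(yb)) / sqrt(s2)
    }, 0))
    q <- quantile(bd, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  } else {
    # invert the noncentral-t CDF for the ncp bounds of t = d / sqrt(1/n1 + 1/n2)
    scl <- sqrt(1 / n1 + 1 / n2)
    tv <- d / scl
    df <- n1 + n2 - 2
    bound <- function(p) {
      # far-tail ncp probes trip pt()'s precision warning; harmless here
      f <- function(ncp) suppressWarnings(pt(tv, df, ncp)) - p
      lo <- tv - 10 - 10 * abs(tv); hi <- tv + 10 + 10 * abs(tv)
      uniroot(f, c(lo, hi), extendInt = "yes")$root
    }
    q <- c(bound(1 - a), bound(a)) * scl
  }
  out$ci_low <- min(q); out$ci_high <- max(q)
  out
}

#' Effect-size table over strata or criteria constellations
#'
#' For each group (exact-k stratum or criteria constellation) with at least
#' `min_n` cases, computes Cohen's d of the per-subject mask means against
#' the full single control pool, for every mask. Groups below `min_n` are
#' omitted (and reported via `message()`).
#'
#' @param subjects Subject table.
#' @param means N x M matrix from [mask_means()] (rows follow `subjects`).
#' @param grouping "constellations" or "strata".
#' @param min_n Minimum cases per group (default 10).
#' @param ci,n_boot,seed Passed to [cohens_d()].
#' @return Data frame with one row per (group, mask): `mask_id`,
#'   `group_type`, `k`, `constellation_id` (NA for strata rows), `n_case`,
#'   `n_control`, `d`, `ci_low`, `ci_high`.
#' @export
effect_table <- function(subjects, means, grouping = c("constellations", "strata"),
                         min_n = 10, ci = FALSE, n_boot = 1000, seed = 1) {
  grouping <- match.arg(grouping)
  if (is.null(colnames(means)) || ncol(means) == 0) stop("no masks available")
  strata <- assign_strata(subjects)
  ctrl <- which(subjects$group == "control")
  groups <- if (grouping == "strata") {
    lapply(1:6, function(k) list(k = k, constellation_id = NA_integer_,
                                 ids = strata$subject_id[strata$k == k]))
  } else {
    cons <- enumerate_constellations(6)
    lapply(seq_len(nrow(cons)), function(i) {
      cid <- cons$constellation_id[i]
      list(k = cons$k[i], constellation_id = cid,
           ids = strata$subject_id[strata$constellation_id == cid])
    })
  }
  rows <- list()
  dropped <- 0L
  for (gr in groups) {
    if (length(gr$ids) < min_n) {
      if (length(gr$ids) > 0) dropped <- dropped + 1L
      next
    }
    idx <- match(gr$ids, subjects$subject_id)
    for (m in colnames(means)) {
      es <- cohens_d(means[idx, m], means[ctrl, m], ci = ci,
                     n_boot = n_boot, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        mask_id = m, group_type = grouping, k = gr$k,
        constellation_id = gr$constellation_id,
        n_case = es$n_case, n_control = es$n_control,
        d = es$d, ci_low = es$ci_low, ci_high = es$ci_high)
    }
  }
  if (dropped > 0)
    message(dropped, " group(s) below the minimum of ", min_n,
            " participants were omitted")
  if (!length(rows)) stop("no group reached the minimum size")
  do.call(rbind, rows)
}
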