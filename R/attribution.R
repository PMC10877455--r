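#' Difference in effect size per criterion and mask
#'
#' The attribution statistic: for each mask and each criterion, the
#' unweighted mean of Cohen's d over the retained constellations that
#' contain the criterion minus the unweighted mean over those that lack
#' it. A criterion with an empty side for a mask is flagged undefined
#' (`delta_es = NA`), never fabricated. A subject-count-weighted variant is
#' available for sensitivity analysis.
#'
#' @param effect_records Constellation-level output of [effect_table()]
#'   (rows with non-NA `constellation_id`).
#' @param weighted Weight constellation means by `n_case` instead of
#'   averaging constellations equally (default FALSE, the primary
#'   definition).
#' @return Data frame `mask_id`, `criterion`, `delta_es`, `n_with`,
#'   `n_without`.
#' @export
attribute_criteria <- function(effect_records, weighted = FALSE) {
  rec <- effect_records[!is.na(effect_records$constellation_id), , drop = FALSE]
  if (!nrow(rec)) stop("no constellation-level effect records")
  rows <- list()
  for (m in unique(rec$mask_id)) {
    sub <- rec[rec$mask_id == m, ]
    for (j in 1:6) {
      has <- bitwAnd(sub$constellation_id, 2^(j - 1)) > 0
      nw <- sum(has); nwo <- sum(!has)
      delta <- if (nw == 0 || nwo == 0) NA_real_ else if (weighted) {
        sum(sub$d[has] * sub$n_case[has]) / sum(sub$n_case[has]) -
          sum(sub$d[!has] * sub$n_case[!has]) / sum(sub$n_case[!has])
      } else mean(sub$d[has]) - mean(sub$d[!has])
      rows[[length(rows) + 1L]] <- data.frame(
        mask_id = m, criterion = .criteria[j], delta_es = delta,
        n_with = nw, n_without = nwo)
    }
  }
  do.call(rbind, rows)
}

#' Median and IQR of the attribution statistic per criterion
#'
#' Summarises `delta_es` over the masks in scope. Quartiles use the
#' standard linear-interpolation rule (R quantile type 7).
#'
#' @param results Output of [attribute_criteria()].
#' @param mask_ids Optional subset of masks (e.g. one modality or the
#'   functional family); default all.
#' @return Data frame `criterion`, `median`, `q1`, `q3`, `n_masks`.
#' @export
summarize_attribution <- function(results, mask_ids = unique(results$mask_id)) {
  sub <- results[results$mask_id %in% mask_ids & !is.na(results$delta_es), ]
  if (!nrow(sub)) stop("no attribution results in scope")
  out <- lapply(split(sub, factor(sub$criterion, levels = .criteria)), function(s) {
    if (!nrow(s)) return(NULL)
    q <- quantile(s$delta_es, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(criterion = s$criterion[1], median = q[2], q1 = q[1], q3 = q[3],
               n_masks = nrow(s))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
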