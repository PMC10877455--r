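#' Reference demographic counts for the criteria groups
#'
#' Published sex counts and one-decimal percentages for the six
#' lifetime-depression criteria groups, the six exact-k strata, all cases
#' and the single control pool of the UK Biobank imaging cohort that this
#' analysis design targets. Bundled so the demographic arithmetic of the
#' design (percentages from counts) can be re-derived and checked without
#' any data access.
#'
#' @return Data frame with columns `group`, `total`, `n_female`, `n_male`,
#'   `printed_female_pct`, `printed_male_pct`.
#' @export
reference_demographics <- function() {
  path <- system.file("extdata", "criteria_demographics.tsv",
                      package = "depstrat", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute sex percentages from counts
#'
#' Adds `female_pct` and `male_pct` columns, computed from the integer
#' counts and rounded to one decimal, for comparison against the printed
#' values.
#'
#' @param counts Data frame as returned by [reference_demographics()].
#' @return The input with computed percentage columns appended.
#' @export
recompute_sex_percentages <- function(counts = reference_demographics()) {
  stopifnot(all(counts$n_female + counts$n_male == counts$total))
  counts$female_pct <- round(100 * counts$n_female / counts$total, 1)
  counts$male_pct <- round(100 * counts$n_male / counts$total, 1)
  counts
}
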