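#' Enumerate all criteria constellations
#'
#' All non-empty subsets of n criteria, canonically ordered by (number of
#' criteria, numeric bit value). Bit i (value 2^(i-1)) corresponds to the
#' i-th criterion in [criteria_names()] order.
#'
#' @param n_criteria Number of criteria (>= 1); default 6.
#' @return Data frame with `constellation_id` (bit mask), `k` (popcount)
#'   and `pattern` (e.g. "antidep+icd10" for the 6-criteria case).
#' @export
#' @examples
#' nrow(enumerate_constellations(6))  # 63
enumerate_constellations <- function(n_criteria = 6) {
  stopifnot(n_criteria >= 1)
  ids <- seq_len(2^n_criteria - 1)
  k <- vapply(ids, function(x) sum(bitwAnd(x, 2^(0:(n_criteria - 1))) > 0), 0L)
  ord <- order(k, ids)
  nm <- if (n_criteria == 6) .criteria else paste0("c", seq_len(n_criteria))
  pat <- vapply(ids, function(x)
    paste(nm[bitwAnd(x, 2^(0:(n_criteria - 1))) > 0], collapse = "+"), "")
  data.frame(constellation_id = ids[ord], k = k[ord], pattern = pat[ord])
}

# Bit-mask constellation id from a logical matrix of criteria columns.
.constellation_id <- function(bits) {
  as.integer(as.matrix(bits) %*% 2^(0:(ncol(bits) - 1)))
}

#' Assign cases to exact-k strata and constellations
#'
#' Every case belongs to exactly one exact-k stratum (it met exactly k, not
#' at least k, criteria) and exactly one constellation (the specific subset
#' it met), so the strata partition the cases.
#'
#' @param subjects Subject table with `crit_*` columns and `group`.
#' @return Data frame `subject_id`, `k`, `constellation_id` for cases.
#' @export
assign_strata <- function(subjects) {
  cases <- subjects[subjects$group == "case", , drop = FALSE]
  bits <- as.matrix(cases[paste0("crit_", .criteria)]) > 0
  k <- as.integer(rowSums(bits))
  if (any(k == 0)) stop("case with all-false criteria profile")
  data.frame(subject_id = cases$subject_id, k = k,
             constellation_id = .constellation_id(bits))
}

#' 1:1 control matching within sex
#'
#' Greedy nearest-neighbour matching without replacement: cases are
#' processed in a seeded random order; each is paired with the unused
#' control of the same sex minimising Euclidean distance on z-scored
#' matching variables (default age and years of education). Cases left
#' without a same-sex control are reported unmatched.
#'
#' @param cases,control_pool Subject tables.
#' @param vars Continuous matching variables (z-scored over both tables).
#' @param seed Integer seed fixing the processing order.
#' @return List with `pairs` (data frame case_id, control_id, distance) and
#'   `unmatched` (character vector of case ids).
#' @export
match_controls <- function(cases, control_pool,
                           vars = c("age", "education_years"), seed = 1) {
  if (nrow(control_pool) == 0) stop("empty control pool")
  all_v <- rbind(cases[vars], control_pool[vars])
  mu <- colMeans(all_v); sdv <- vapply(all_v, sd, 0)
  sdv[sdv == 0] <- 1
  zc <- scale(cases[vars], mu, sdv)
  zp <- scale(control_pool[vars], mu, sdv)
  used <- rep(FALSE, nrow(control_pool))
  ord <- .with_seed(seed, sample.int(nrow(cases)))
  pairs <- vector("list", nrow(cases))
  unmatched <- character()
  for (i in ord) {
    ok <- !used & control_pool$sex == cases$sex[i]
    if (!any(ok)) {
      unmatched <- c(unmatched, cases$subject_id[i])
      next
    }
    d2 <- colSums((t(zp[ok, , drop = FALSE]) - as.numeric(zc[i, ]))^2)
    j <- which(ok)[which.min(d2)]
    used[j] <- TRUE
    pairs[[i]] <- data.frame(case_id = cases$subject_id[i],
                             control_id = control_pool$subject_id[j],
                             distance = sqrt(min(d2)))
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
  if (is.null(pairs))
    pairs <- data.frame(case_id = character(), control_id = character(),
                        distance = numeric())
  list(pairs = pairs, unmatched = unmatched)
}
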