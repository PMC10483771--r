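#' Neutrophil-to-lymphocyte ratio
#'
#' NLR = neutrophil count / lymphocyte count, both in 10^9/L.
#'
#' @param neut Neutrophil count(s), >= 0.
#' @param lymph Lymphocyte count(s), > 0.
#' @return Numeric ratio(s).
#' @examples
#' compute_nlr(4.0, 2.0)
#' @export
compute_nlr <- function(neut, lymph) {
  if (any(neut < 0, na.rm = TRUE)) {
    stop("neutrophil count must be >= 0", call. = FALSE)
  }
  if (any(lymph <= 0, na.rm = TRUE)) {
    stop("lymphocyte count must be > 0 to form the NLR", call. = FALSE)
  }
  neut / lymph
}

#' Assign mid-rank deciles
#'
#' Observation i receives decile `ceiling(10 * r_i / n)` where `r_i` is its
#' mid-rank (ties get the average of their ranks). Tied values therefore
#' always share a decile, the assignment is invariant to monotone
#' transformations of the values, and every index lies in 1-10.
#'
#' @param values Numeric vector, length >= 10, all finite.
#' @return Integer vector of decile indices, same order as `values`.
#' @examples
#' assign_deciles(1:10)
#' assign_deciles(rep(7, 50))[1]  # all tied -> decile 6
#' @export
assign_deciles <- function(values) {
  n <- length(values)
  if (n < 10) {
    stop("at least 10 observations are required to form deciles (got ",
         n, ")", call. = FALSE)
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop("non-finite value at row ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r <- rank(values, ties.method = "average")
  as.integer(ceiling(10 * r / n))
}

#' Map a decile index to its inflammation score
#'
#' Fixed map: deciles 1-4 score -4 to -1, deciles 5 and 6 score 0, deciles
#' 7-10 score 1 to 4. Higher biomarker levels therefore always score
#' higher, reflecting greater low-grade inflammation.
#'
#' @param decile Integer vector with entries in 1-10.
#' @return Integer scores in \{-4..-1, 0, 1..4\}.
#' @examples
#' decile_to_score(c(1, 5, 6, 10))
#' @export
decile_to_score <- function(decile) {
  if (any(!decile %in% 1:10)) {
    stop("decile index must be an integer in 1..10", call. = FALSE)
  }
  map <- c(-4L, -3L, -2L, -1L, 0L, 0L, 1L, 2L, 3L, 4L)
  map[as.integer(decile)]
}

#' Compute the low-grade inflammation (LGI) score for a cohort
#'
#' For each patient: form the NLR, assign cohort-internal mid-rank deciles
#' to CRP, leukocyte count (WBC), platelet count (PLT) and NLR, map each
#' decile through [decile_to_score()], and sum the four marker scores. The
#' total ranges from -16 (all four markers in the bottom decile) to 16 (all
#' in the top decile). Deciles are computed within the analyzed sample, not
#' against external reference ranges.
#'
#' Records with a non-positive lymphocyte count cannot form the NLR; they
#' are excluded from scoring (complete-case stance) and reported in the
#' `excluded` attribute.
#'
#' @param cohort Cohort data frame with columns `crp`, `wbc`, `neut`,
#'   `lymph`, `plt` (and optionally `id`); at least 10 scoreable rows.
#' @return `data.frame` of class `lgi_scores`, one row per scoreable record
#'   in input order: `id`, `nlr`, `decile_crp`, `decile_wbc`, `decile_plt`,
#'   `decile_nlr`, `score_crp`, `score_wbc`, `score_plt`, `score_nlr`,
#'   `lgi_score`, `lgi_quartile`. Attributes: `quartile_cuts` (realized cut
#'   points) and `excluded` (ids of records dropped at the NLR step).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 50, seed = 1))
#' scores <- compute_lgi_scores(cohort)
#' range(scores$lgi_score)
#' @export
compute_lgi_scores <- function(cohort) {
  needed <- c("crp", "wbc", "neut", "lymph", "plt")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing biomarker columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- if ("id" %in% names(cohort)) as.character(cohort$id)
         else as.character(seq_len(nrow(cohort)))

  scoreable <- cohort$lymph > 0 & !is.na(cohort$lymph)
  excluded <- ids[!scoreable]
  if (length(excluded)) {
    warning(sprintf(
      "%d record(s) excluded from LGI scoring (non-positive lymphocyte count): %s",
      length(excluded), paste(excluded, collapse = ", ")), call. = FALSE)
  }
  dat <- cohort[scoreable, needed]
  ids <- ids[scoreable]
  if (nrow(dat) < 10) {
    stop("at least 10 scoreable records are required (got ", nrow(dat), ")",
         call. = FALSE)
  }

  nlr <- compute_nlr(dat$neut, dat$lymph)
  marker_values <- list(crp = dat$crp, wbc = dat$wbc, plt = dat$plt,
                        nlr = nlr)
  deciles <- lapply(marker_values, assign_deciles)
  scores <- lapply(deciles, decile_to_score)
  lgi <- scores$crp + scores$wbc + scores$plt + scores$nlr

  qg <- quartile_groups(lgi)

  out <- data.frame(
    id = ids, nlr = nlr,
    decile_crp = deciles$crp, decile_wbc = deciles$wbc,
    decile_plt = deciles$plt, decile_nlr = deciles$nlr,
    score_crp = scores$crp, score_wbc = scores$wbc,
    score_plt = scores$plt, score_nlr = scores$nlr,
    lgi_score = lgi, lgi_quartile = qg$group,
    stringsAsFactors = FALSE
  )
  attr(out, "quartile_cuts") <- qg$cuts
  attr(out, "excluded") <- excluded
  class(out) <- c("lgi_scores", "data.frame")
  out
}

#' @export
print.lgi_scores <- function(x, ...) {
  cat(sprintf("LGI scores for %d patients (range %d to %d)\n",
              nrow(x), min(x$lgi_score), max(x$lgi_score)))
  cuts <- attr(x, "quartile_cuts")
  if (length(cuts)) {
    cat(sprintf("  quartile cut points (upper bounds of Q1-Q3): %s\n",
                paste(cuts, collapse = ", ")))
  }
  excl <- attr(x, "excluded")
  if (length(excl)) cat(sprintf("  %d record(s) excluded\n", length(excl)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Partition scores into cohort-relative quartile groups
#'
#' Groups by the empirical 25/50/75 percentiles using the same mid-rank
#' rule as [assign_deciles()] (group = `ceiling(4 * midrank / n)`), so tied
#' scores always land in the same group. The realized cut points (the
#' largest score in each of groups 1-3) are returned for reporting in the
#' "Q1 (<= -5)" style of baseline tables.
#'
#' @param scores Numeric vector, length >= 4.
#' @return List with `group` (integer 1-4, input order) and `cuts` (numeric
#'   length 3, upper bounds of groups 1-3). A degenerate distribution (all
#'   scores equal) yields a single group with a warning and no cuts.
#' @examples
#' quartile_groups(c(-16, -8, 0, 8))$group
#' @export
quartile_groups <- function(scores) {
  n <- length(scores)
  if (n < 4) stop("need at least 4 scores for quartiles", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (length(unique(scores)) == 1L) {
    warning("degenerate score distribution (all equal): single group",
            call. = FALSE)
    return(list(group = rep(1L, n), cuts = numeric(0)))
  }
  r <- rank(scores, ties.method = "average")
  group <- as.integer(ceiling(4 * r / n))
  cuts <- vapply(1:3, function(g) {
    if (any(group <= g)) max(scores[group <= g]) else NA_real_
  }, numeric(1))
  list(group = group, cuts = cuts)
}
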