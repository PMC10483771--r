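#' Classify stroke severity from an NIHSS score
#'
#' Severe (moderate/severe) stroke is an NIHSS score strictly greater
#' than 5; a score of 5 or less is mild.
#'
#' @param nihss Non-negative integer NIHSS score(s); `NA` passes through.
#' @return Logical: `TRUE` for severe.
#' @examples
#' classify_severity(c(5, 6))
#' @export
classify_severity <- function(nihss) {
  if (any(nihss < 0, na.rm = TRUE)) {
    stop("NIHSS score must be >= 0", call. = FALSE)
  }
  nihss > 5
}

#' Detect early neurological deterioration (END)
#'
#' END is an increase of at least 2 NIHSS points between baseline and day 7.
#' A missing value on either side yields `NA` (the record is excluded from
#' END analyses rather than guessed).
#'
#' @param nihss_baseline,nihss_day7 Non-negative integer NIHSS scores.
#' @return Logical END flag(s).
#' @examples
#' detect_end(2, 4)   # TRUE
#' detect_end(4, 2)   # FALSE (improvement)
#' @export
detect_end <- function(nihss_baseline, nihss_day7) {
  if (any(nihss_baseline < 0, na.rm = TRUE) ||
      any(nihss_day7 < 0, na.rm = TRUE)) {
    stop("NIHSS scores must be >= 0", call. = FALSE)
  }
  (nihss_day7 - nihss_baseline) >= 2
}

#' Dichotomize the 90-day modified Rankin Scale
#'
#' mRS 0-1 is an excellent functional outcome; mRS 2-6 (including death,
#' mRS 6) is poor.
#'
#' @param mrs_90d Integer mRS value(s) in 0-6.
#' @return Character vector, `"excellent"` or `"poor"`.
#' @examples
#' classify_outcome(c(1, 2, 6))
#' @export
classify_outcome <- function(mrs_90d) {
  if (any(!is.na(mrs_90d) & (mrs_90d < 0 | mrs_90d > 6))) {
    stop("mRS must lie in 0..6", call. = FALSE)
  }
  ifelse(is.na(mrs_90d), NA_character_,
         ifelse(mrs_90d <= 1, "excellent", "poor"))
}

#' Derive threshold-defined vascular risk factors
#'
#' Applies the clinical definitions: hypertension is SBP >= 140 mmHg,
#' DBP >= 90 mmHg or antihypertensive use; diabetes is fasting glucose
#' > 7.0 mmol/L or antidiabetic use (a single fasting measurement stands in
#' for the repeat-measurement criterion, since one value per record
#' exists); dyslipidemia is total cholesterol > 5.18 mmol/L or
#' triglycerides > 1.7 mmol/L. Missing raw fields yield `NA` flags unless a
#' medication flag already decides the factor.
#'
#' @param record Data frame (one or more rows) with columns `sbp`, `dbp`,
#'   `tc`, `tg`, `fbg`, `antihypertensives`, `antidiabetics`.
#' @return Data frame with logical columns `hypertension`, `diabetes`,
#'   `dyslipidemia`.
#' @examples
#' derive_risk_factors(data.frame(sbp = 140, dbp = 80, tc = 5.2, tg = 1.0,
#'   fbg = 5.5, antihypertensives = 0, antidiabetics = 0))
#' @export
derive_risk_factors <- function(record) {
  or_na <- function(a, b) {
    # TRUE wins over NA: a decided criterion overrides a missing one
    out <- a | b
    out[is.na(out) & (a %in% TRUE | b %in% TRUE)] <- TRUE
    out
  }
  htn <- or_na(or_na(record$sbp >= 140, record$dbp >= 90),
               record$antihypertensives == 1)
  dm <- or_na(record$fbg > 7.0, record$antidiabetics == 1)
  dys <- or_na(record$tc > 5.18, record$tg > 1.7)
  data.frame(hypertension = htn, diabetes = dm, dyslipidemia = dys)
}

#' Append endpoint columns to a scored cohort
#'
#' Adds `severe_baseline`, `severe_day7`, `end_flag` and `poor_90d` (0/1,
#' `NA` where an input is missing) plus the complementary `excellent_90d`.
#'
#' @param cohort Cohort data frame with `nihss_baseline`, `nihss_day7` and
#'   `mrs_90d`.
#' @return The cohort with five endpoint columns appended.
#' @export
add_endpoints <- function(cohort) {
  cohort$severe_baseline <- as.integer(classify_severity(cohort$nihss_baseline))
  cohort$severe_day7 <- as.integer(classify_severity(cohort$nihss_day7))
  cohort$end_flag <- as.integer(detect_end(cohort$nihss_baseline,
                                           cohort$nihss_day7))
  out90 <- classify_outcome(cohort$mrs_90d)
  cohort$poor_90d <- as.integer(out90 == "poor")
  cohort$excellent_90d <- as.integer(out90 == "excellent")
  cohort
}
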