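#' Fixed column schema of a cohort CSV
#'
#' @return Character vector of the 29 column names, in file order.
#' @export
cohort_schema <- function() {
  c("id", "age", "male", "hypertension", "diabetes", "dyslipidemia", "chd",
    "af", "smoking", "drinking", "prior_stroke", "antihypertensives",
    "antidiabetics", "statins", "sbp", "dbp", "tc", "tg", "fbg", "crp",
    "wbc", "neut", "lymph", "plt", "nihss_baseline", "nihss_day7",
    "mrs_baseline", "mrs_90d", "toast_subtype")
}

.flag_cols <- c("male", "hypertension", "diabetes", "dyslipidemia", "chd",
                "af", "smoking", "drinking", "prior_stroke",
                "antihypertensives", "antidiabetics", "statins")
.biomarker_cols <- c("crp", "wbc", "neut", "lymph", "plt")

#' Write a cohort to CSV
#'
#' Writes the fixed schema (see [cohort_schema()]) as UTF-8 CSV with "."
#' decimal points and 0/1 flags, suitable for lossless round-tripping via
#' [read_cohort()].
#'
#' @param cohort Cohort data frame with all schema columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  missing_cols <- setdiff(cohort_schema(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing schema columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(cohort[, cohort_schema()], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Enforces the fixed schema and record invariants: every schema column
#' present, no unknown columns, numeric biomarkers, NIHSS >= 0, mRS in 0-6
#' and strictly positive biomarker values. A record whose neutrophil count
#' exceeds its leukocyte count is kept but flagged with a warning (real
#' panels occasionally violate the inequality).
#'
#' @param path Path to a cohort CSV written by [write_cohort()] (or any file
#'   with the same schema).
#' @return Validated cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", colClasses = "character")
  validate_cohort(raw, coerce = TRUE)
}

#' Validate a cohort data frame against the schema and invariants
#'
#' @param cohort Data frame to check.
#' @param coerce If `TRUE`, columns arrive as character (fresh from CSV) and
#'   are parsed to their schema types, with row-indexed parse errors.
#' @return The validated (and possibly coerced) data frame.
#' @export
validate_cohort <- function(cohort, coerce = FALSE) {
  schema <- cohort_schema()
  missing_cols <- setdiff(schema, names(cohort))
  unknown_cols <- setdiff(names(cohort), schema)
  if (length(missing_cols) || length(unknown_cols)) {
    parts <- c(
      if (length(missing_cols))
        paste("missing:", paste(missing_cols, collapse = ", ")),
      if (length(unknown_cols))
        paste("unknown:", paste(unknown_cols, collapse = ", "))
    )
    stop("cohort schema error - ", paste(parts, collapse = "; "),
         call. = FALSE)
  }
  cohort <- cohort[, schema]

  if (coerce) {
    num_cols <- setdiff(schema, c("id", "toast_subtype"))
    for (col in num_cols) {
      parsed <- suppressWarnings(as.numeric(cohort[[col]]))
      bad <- which(is.na(parsed) & !(cohort[[col]] %in% c("", "NA")))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at row %s",
                     col, paste(bad, collapse = ", ")), call. = FALSE)
      }
      cohort[[col]] <- parsed
    }
    int_cols <- c(.flag_cols, "nihss_baseline", "nihss_day7",
                  "mrs_baseline", "mrs_90d")
    for (col in int_cols) cohort[[col]] <- as.integer(cohort[[col]])
  }

  check_rows <- function(bad, msg) {
    if (length(bad)) {
      stop(sprintf("%s at row %s", msg, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  for (col in .flag_cols) {
    v <- cohort[[col]]
    check_rows(which(!is.na(v) & !(v %in% c(0L, 1L))),
               sprintf("flag column '%s' must be 0/1", col))
  }
  for (col in c("mrs_baseline", "mrs_90d")) {
    v <- cohort[[col]]
    check_rows(which(!is.na(v) & (v < 0 | v > 6)),
               sprintf("'%s' outside mRS range 0-6", col))
  }
  for (col in c("nihss_baseline", "nihss_day7")) {
    v <- cohort[[col]]
    check_rows(which(!is.na(v) & v < 0), sprintf("'%s' must be >= 0", col))
  }
  for (col in .biomarker_cols) {
    v <- cohort[[col]]
    check_rows(which(!is.na(v) & v <= 0),
               sprintf("biomarker '%s' must be > 0", col))
  }
  n_inconsistent <- sum(cohort$neut > cohort$wbc, na.rm = TRUE)
  if (n_inconsistent > 0) {
    warning(sprintf("%d record(s) have neutrophil count > leukocyte count",
                    n_inconsistent), call. = FALSE)
  }
  cohort
}
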