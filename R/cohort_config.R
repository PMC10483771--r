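#' Configuration for the synthetic stroke cohort generator
#'
#' Builds a validated configuration object for [simulate_cohort()]. Defaults
#' reproduce the marginal structure of a hospital registry of 876 acute
#' ischemic stroke patients: 58% male, median age 70 years (IQR 60.5-78),
#' hypertension 69.2%, diabetes 24.2%, dyslipidemia 43.9%, coronary heart
#' disease 13%, atrial fibrillation 10.6%, smoking 29.2%, drinking 26.8%,
#' prior stroke 11%, and TOAST subtype proportions LAA 35.4% / CE 13.7% /
#' SAA 40.9% / Other 10%.
#'
#' Biomarkers are drawn log-normally; each log-marker loads on a single
#' latent standard-normal inflammation factor, which also enters the
#' logistic outcome links, so the true strength of the inflammation-outcome
#' association is known and recoverable. Baseline NIHSS is a negative
#' binomial count whose log-mean carries the latent loading (severity,
#' defined as NIHSS > 5, therefore inherits the inflammation link rather
#' than being drawn separately).
#'
#' @param n_patients Number of patients to generate (positive integer).
#' @param prop_male Proportion male, in \[0, 1\].
#' @param age_median,age_iqr_low,age_iqr_high Age location and IQR in years;
#'   ages are drawn normal (sd from the IQR width) and truncated to 18-100.
#' @param risk_factor_prevalences Named numeric vector of Bernoulli
#'   prevalences for `hypertension`, `diabetes`, `dyslipidemia`, `chd`,
#'   `af`, `smoking`, `drinking`, `prior_stroke`.
#' @param biomarker_params Named list, one entry per marker (`crp`, `wbc`,
#'   `neut`, `lymph`, `plt`), each `c(meanlog =, sdlog =)` on the natural-log
#'   scale. Units: CRP mg/L; cell counts 10^9/L.
#' @param inflammation_loading Named numeric vector: coefficient of the
#'   latent factor on each log-marker. Set all to 0 for a null cohort in
#'   which the composite score carries no signal.
#' @param outcome_model List with components `end` (`intercept`,
#'   `inflammation`) and `poor_90d` (`intercept`, `inflammation`, `age`,
#'   `nihss`), the log-odds coefficients of the logistic outcome links.
#'   Age enters centred at 70 years.
#' @param nihss_baseline_dist List `size`, `mu`, `inflammation`: negative
#'   binomial size and mean for baseline NIHSS, and the latent-factor
#'   loading on its log-mean.
#' @param toast_probs Multinomial probabilities for TOAST subtypes
#'   (named `LAA`, `CE`, `SAA`, `Other`); must sum to 1.
#' @param seed Integer seed; the generator touches no global RNG state.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [simulate_cohort()], [read_cohort_config()]
#' @examples
#' cfg <- cohort_config(n_patients = 200, seed = 7)
#' cfg$risk_factor_prevalences[["hypertension"]]
#' @export
cohort_config <- function(n_patients = 876,
                          prop_male = 0.58,
                          age_median = 70, age_iqr_low = 60.5, age_iqr_high = 78,
                          risk_factor_prevalences = c(
                            hypertension = 0.692, diabetes = 0.242,
                            dyslipidemia = 0.439, chd = 0.130, af = 0.106,
                            smoking = 0.292, drinking = 0.268,
                            prior_stroke = 0.110
                          ),
                          biomarker_params = list(
                            crp   = c(meanlog = log(2),    sdlog = 1.00),
                            wbc   = c(meanlog = log(6.5),  sdlog = 0.25),
                            neut  = c(meanlog = log(4.0),  sdlog = 0.30),
                            lymph = c(meanlog = log(1.8),  sdlog = 0.30),
                            plt   = c(meanlog = log(220),  sdlog = 0.25)
                          ),
                          inflammation_loading = c(
                            crp = 0.80, wbc = 0.15, neut = 0.25,
                            lymph = -0.15, plt = 0.05
                          ),
                          outcome_model = list(
                            end = c(intercept = stats::qlogis(0.08),
                                    inflammation = 0.5),
                            poor_90d = c(intercept = -2.0, inflammation = 0.6,
                                         age = 0.04, nihss = 0.25)
                          ),
                          nihss_baseline_dist = list(size = 1.3, mu = 2.6,
                                                     inflammation = 0.35),
                          toast_probs = c(LAA = 0.354, CE = 0.137,
                                          SAA = 0.409, Other = 0.100),
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, prop_male = prop_male,
    age_median = age_median, age_iqr_low = age_iqr_low,
    age_iqr_high = age_iqr_high,
    risk_factor_prevalences = risk_factor_prevalences,
    biomarker_params = biomarker_params,
    inflammation_loading = inflammation_loading,
    outcome_model = outcome_model,
    nihss_baseline_dist = nihss_baseline_dist,
    toast_probs = toast_probs,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

.markers <- c("crp", "wbc", "neut", "lymph", "plt")
.risk_factors <- c("hypertension", "diabetes", "dyslipidemia", "chd", "af",
                   "smoking", "drinking", "prior_stroke")

#' Validate a cohort configuration
#'
#' Checks every field invariant (proportions in \[0,1\], positive scales,
#' positive n, complete marker and risk-factor sets) and fails with an error
#' naming the offending field.
#'
#' @param cfg A `cohort_config` object (or bare list with the same fields).
#' @return The validated config, invisibly classed `cohort_config`.
#' @export
validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid cohort config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 1 ||
      cfg$n_patients != round(cfg$n_patients)) {
    fail("n_patients", "must be a positive integer")
  }
  if (!is.numeric(cfg$prop_male) || cfg$prop_male < 0 || cfg$prop_male > 1) {
    fail("prop_male", "must be a proportion in [0, 1]")
  }
  if (!is.numeric(cfg$age_median) || cfg$age_median <= 0) {
    fail("age_median", "must be positive")
  }
  if (cfg$age_iqr_low >= cfg$age_iqr_high) {
    fail("age_iqr_low", "IQR bounds must satisfy low < high")
  }
  rf <- cfg$risk_factor_prevalences
  missing_rf <- setdiff(.risk_factors, names(rf))
  if (length(missing_rf)) {
    fail("risk_factor_prevalences",
         paste("missing factors:", paste(missing_rf, collapse = ", ")))
  }
  if (any(rf < 0 | rf > 1)) {
    bad <- names(rf)[rf < 0 | rf > 1]
    fail("risk_factor_prevalences",
         paste("not in [0, 1]:", paste(bad, collapse = ", ")))
  }
  missing_bm <- setdiff(.markers, names(cfg$biomarker_params))
  if (length(missing_bm)) {
    fail("biomarker_params",
         paste("missing markers:", paste(missing_bm, collapse = ", ")))
  }
  for (m in .markers) {
    p <- cfg$biomarker_params[[m]]
    if (!all(c("meanlog", "sdlog") %in% names(p)) || p[["sdlog"]] <= 0) {
      fail("biomarker_params", sprintf("marker '%s' needs meanlog and sdlog > 0", m))
    }
  }
  missing_ld <- setdiff(.markers, names(cfg$inflammation_loading))
  if (length(missing_ld)) {
    fail("inflammation_loading",
         paste("missing markers:", paste(missing_ld, collapse = ", ")))
  }
  om <- cfg$outcome_model
  if (!all(c("intercept", "inflammation") %in% names(om$end))) {
    fail("outcome_model", "end needs 'intercept' and 'inflammation'")
  }
  if (!all(c("intercept", "inflammation", "age", "nihss") %in%
           names(om$poor_90d))) {
    fail("outcome_model",
         "poor_90d needs 'intercept', 'inflammation', 'age', 'nihss'")
  }
  nd <- cfg$nihss_baseline_dist
  if (!all(c("size", "mu", "inflammation") %in% names(nd)) ||
      nd$size <= 0 || nd$mu <= 0) {
    fail("nihss_baseline_dist", "needs size > 0, mu > 0 and inflammation")
  }
  tp <- cfg$toast_probs
  if (!all(c("LAA", "CE", "SAA", "Other") %in% names(tp)) ||
      any(tp < 0) || abs(sum(tp) - 1) > 1e-8) {
    fail("toast_probs", "needs LAA/CE/SAA/Other probabilities summing to 1")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    fail("seed", "must be a single integer")
  }
  class(cfg) <- "cohort_config"
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic stroke cohort configuration\n")
  cat(sprintf("  n_patients: %d   seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  prop_male: %.3f   age: median %.1f [%.1f, %.1f]\n",
              x$prop_male, x$age_median, x$age_iqr_low, x$age_iqr_high))
  cat("  risk factor prevalences:\n")
  cat(sprintf("    %s\n", paste(sprintf("%s=%.3f",
      names(x$risk_factor_prevalences), x$risk_factor_prevalences),
      collapse = " ")))
  cat("  inflammation loadings:\n")
  cat(sprintf("    %s\n", paste(sprintf("%s=%.2f",
      names(x$inflammation_loading), x$inflammation_loading),
      collapse = " ")))
  invisible(x)
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' The file holds any subset of the [cohort_config()] arguments; omitted
#' keys fall back to the defaults. Nested keys (`biomarker_params`,
#' `outcome_model`, ...) follow the same structure as the R arguments.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # yaml gives named lists where the constructor expects named vectors
  for (k in c("risk_factor_prevalences", "inflammation_loading",
              "toast_probs")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  if (!is.null(raw$biomarker_params)) {
    raw$biomarker_params <- lapply(raw$biomarker_params, unlist)
  }
  if (!is.null(raw$outcome_model)) {
    raw$outcome_model <- lapply(raw$outcome_model, unlist)
  }
  do.call(cohort_config, raw)
}
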