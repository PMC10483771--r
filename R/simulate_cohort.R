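#' Simulate a synthetic acute ischemic stroke cohort
#'
#' Draws `n_patients` patient records from the generative model described in
#' [cohort_config()]. One latent standard-normal inflammation factor per
#' patient links the log-scale blood biomarkers to baseline NIHSS, early
#' neurological deterioration (END) and the 90-day functional outcome, so
#' downstream association analyses can be checked against known truth.
#'
#' Generation order per patient: latent factor; demographics and risk-factor
#' flags; medication flags conditional on the risk factors; blood pressure,
#' lipids and glucose shifted by the corresponding flags; biomarkers
#' log-normal with the latent loading; baseline NIHSS negative binomial with
#' the latent loading on its log-mean; day-7 NIHSS as baseline plus a
#' perturbation whose probability of a >= 2-point rise follows the END
#' logistic link; 90-day mRS dichotomy from the poor-outcome logistic link,
#' then an mRS value consistent with it; TOAST subtype multinomial.
#'
#' All randomness is consumed from a private RNG stream seeded by
#' `config$seed`; the caller's `.Random.seed` is untouched and the same
#' config always yields an identical cohort.
#'
#' @param config A [cohort_config()] object.
#' @return A `data.frame` with one row per patient and the fixed cohort
#'   schema (see [cohort_schema()]): identifiers, demographics, risk factor
#'   and medication flags (0/1), vitals and chemistry, the five blood
#'   biomarkers, NIHSS at baseline and day 7, mRS at baseline and day 90,
#'   and TOAST subtype.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 100, seed = 42))
#' nrow(cohort)
#' mean(cohort$hypertension)
#' @export
simulate_cohort <- function(config) {
  config <- validate_cohort_config(config)
  n <- config$n_patients

  # private RNG stream: stash and restore any global state
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)

  f <- stats::rnorm(n)  # latent inflammation factor

  age_sd <- (config$age_iqr_high - config$age_iqr_low) / 1.349
  age <- round(pmin(100, pmax(18, stats::rnorm(n, config$age_median, age_sd))), 1)
  male <- stats::rbinom(n, 1L, config$prop_male)

  rf <- config$risk_factor_prevalences
  flags <- sapply(.risk_factors, function(k) stats::rbinom(n, 1L, rf[[k]]))
  colnames(flags) <- .risk_factors
  flags <- as.data.frame(flags)

  # medication use conditional on the matching risk factor
  antihypertensives <- flags$hypertension * stats::rbinom(n, 1L, 0.60)
  antidiabetics <- flags$diabetes * stats::rbinom(n, 1L, 0.60)
  statins <- stats::rbinom(n, 1L, 0.20 + 0.25 * flags$dyslipidemia)

  # vitals / chemistry, shifted by the flags so threshold-derived factors
  # roughly agree with the recorded ones
  sbp <- round(stats::rnorm(n, 148 + 10 * flags$hypertension, 18))
  dbp <- round(stats::rnorm(n, 85 + 5 * flags$hypertension, 11))
  tc <- round(exp(stats::rnorm(n, log(4.4) + 0.18 * flags$dyslipidemia, 0.18)), 2)
  tg <- round(exp(stats::rnorm(n, log(1.25) + 0.30 * flags$dyslipidemia, 0.40)), 2)
  fbg <- round(exp(stats::rnorm(n, log(5.3) + 0.35 * flags$diabetes, 0.18)), 2)

  eps <- lapply(.markers, function(m) stats::rnorm(n))
  names(eps) <- .markers
  # neutrophils are the dominant leukocyte component: correlate their noise
  # so physiologically impossible neut > wbc panels stay rare (they are
  # flagged, not rejected, downstream)
  eps$neut <- 0.7 * eps$wbc + sqrt(1 - 0.7^2) * eps$neut
  bm <- lapply(.markers, function(m) {
    p <- config$biomarker_params[[m]]
    lam <- config$inflammation_loading[[m]]
    round(exp(p[["meanlog"]] + lam * f + p[["sdlog"]] * eps[[m]]), 3)
  })
  names(bm) <- .markers

  nd <- config$nihss_baseline_dist
  nihss_baseline <- stats::rnbinom(n, size = nd$size,
                                   mu = exp(log(nd$mu) + nd$inflammation * f))

  om_end <- config$outcome_model$end
  p_end <- stats::plogis(om_end[["intercept"]] + om_end[["inflammation"]] * f)
  end_true <- stats::rbinom(n, 1L, p_end)
  # day-7 NIHSS: END forces a rise >= 2; otherwise change stays below +2
  delta <- ifelse(end_true == 1L,
                  2L + stats::rpois(n, 1),
                  pmax(-nihss_baseline,
                       stats::rbinom(n, 4L, 0.3) - 2L))  # support -2..2 capped below +2
  delta[end_true == 0L & delta >= 2L] <- 1L
  nihss_day7 <- pmax(0L, nihss_baseline + delta)

  om_p <- config$outcome_model$poor_90d
  p_poor <- stats::plogis(om_p[["intercept"]] +
                          om_p[["inflammation"]] * f +
                          om_p[["age"]] * (age - 70) +
                          om_p[["nihss"]] * nihss_baseline)
  poor <- stats::rbinom(n, 1L, p_poor)
  mrs_90d <- ifelse(poor == 1L,
                    2L + stats::rbinom(n, 4L, 0.25),
                    stats::rbinom(n, 1L, 0.5))
  mrs_baseline <- pmin(6L, pmax(0L, round(nihss_baseline / 2) +
                                  sample(c(-1L, 0L, 1L), n, replace = TRUE,
                                         prob = c(0.25, 0.5, 0.25)) + 1L))

  toast_subtype <- sample(names(config$toast_probs), n, replace = TRUE,
                          prob = config$toast_probs)

  data.frame(
    id = sprintf("P%05d", seq_len(n)),
    age = age, male = male,
    flags,
    antihypertensives = antihypertensives,
    antidiabetics = antidiabetics,
    statins = statins,
    sbp = sbp, dbp = dbp, tc = tc, tg = tg, fbg = fbg,
    crp = bm$crp, wbc = bm$wbc, neut = bm$neut, lymph = bm$lymph,
    plt = bm$plt,
    nihss_baseline = nihss_baseline, nihss_day7 = nihss_day7,
    mrs_baseline = mrs_baseline, mrs_90d = mrs_90d,
    toast_subtype = toast_subtype,
    stringsAsFactors = FALSE
  )
}
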