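#' Resolve the covariate list for an adjustment tier
#'
#' Three tiers mirror the source tables: `crude` has no covariates;
#' `model1` adjusts for gender and age; `model2` adds smoking, drinking,
#' prior stroke, atrial fibrillation, coronary heart disease, hypertension,
#' diabetes and dyslipidemia. For the 90-day functional outcome, `model2`
#' additionally includes baseline NIHSS; for severity and END it does not
#' (the NIHSS is the severity outcome's own scale).
#'
#' @param outcome Endpoint column name; `"severe_baseline"`,
#'   `"severe_day7"`, `"end_flag"` and `"poor_90d"` are the standard four,
#'   but any binary column may be modelled (treated like a severity
#'   endpoint: no baseline-NIHSS adjustment).
#' @param tier One of `"crude"`, `"model1"`, `"model2"`.
#' @return Character vector of covariate column names (possibly empty).
#' @export
model_covariates <- function(outcome,
                             tier = c("crude", "model1", "model2")) {
  stopifnot(is.character(outcome), length(outcome) == 1)
  tier <- match.arg(tier)
  base1 <- c("male", "age")
  base2 <- c(base1, "smoking", "drinking", "prior_stroke", "af", "chd",
             "hypertension", "diabetes", "dyslipidemia")
  covs <- switch(tier,
    crude = character(0),
    model1 = base1,
    model2 = if (outcome == "poor_90d") c(base2, "nihss_baseline") else base2
  )
  covs
}

.complete_rows <- function(data, cols) {
  stats::complete.cases(data[, cols, drop = FALSE])
}

.check_binary_outcome <- function(y, outcome) {
  tab <- table(y)
  if (length(tab) < 2) {
    stop(sprintf("outcome '%s' has a single class; model not identifiable",
                 outcome), call. = FALSE)
  }
}

.fit_glm <- function(formula, data) {
  warn_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        warn_sep <<- TRUE  # surfaced via the report's separation flag
        invokeRestart("muffleWarning")
      }
    }
  )
  se <- sqrt(diag(stats::vcov(fit)))
  separation <- warn_sep || !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    any(se[-1] > 100, na.rm = TRUE)
  list(fit = fit, separation = separation)
}

#' Fit a quartile logistic regression model
#'
#' Maximum-likelihood logistic regression of a binary endpoint on LGI score
#' quartile indicators (reference = first quartile), with covariates
#' resolved by [model_covariates()]. Odds ratios are `exp(coef)` and 95%
#' confidence intervals are Wald, `exp(coef +- 1.96 * SE)`. Rows with any
#' missing model column are dropped (complete-case) and counted.
#'
#' @param data Data frame with `lgi_quartile` (integer 1-4), the outcome
#'   column and any tier covariates.
#' @param outcome,tier See [model_covariates()].
#' @return Object of class `lgi_model_report`: a list with `outcome`,
#'   `tier`, a `quartiles` data frame (quartile, n, events, or, ci_low,
#'   ci_high, p), `p_trend` (filled by [p_for_trend()]; `NA` here),
#'   `n_used`, `n_dropped`, `converged` and `separation` flags.
#' @examples
#' cohort <- add_endpoints(simulate_cohort(cohort_config(n_patients = 400,
#'   seed = 3)))
#' scores <- compute_lgi_scores(cohort)
#' cohort$lgi_quartile <- scores$lgi_quartile
#' fit_quartile_logistic(cohort, "poor_90d", "crude")
#' @export
fit_quartile_logistic <- function(data, outcome, tier = "crude") {
  covs <- model_covariates(outcome, tier)
  cols <- c(outcome, "lgi_quartile", covs)
  keep <- .complete_rows(data, cols)
  d <- data[keep, cols, drop = FALSE]
  .check_binary_outcome(d[[outcome]], outcome)
  d$lgi_quartile <- factor(d$lgi_quartile, levels = 1:4)

  rhs <- paste(c("lgi_quartile", covs), collapse = " + ")
  res <- .fit_glm(stats::as.formula(paste(outcome, "~", rhs)), d)
  fit <- res$fit
  cf <- summary(fit)$coefficients
  qnames <- paste0("lgi_quartile", 2:4)

  rows <- lapply(1:4, function(q) {
    nq <- sum(d$lgi_quartile == q)
    ev <- sum(d[[outcome]][d$lgi_quartile == q])
    if (q == 1) {
      data.frame(quartile = 1L, n = nq, events = ev, or = 1,
                 ci_low = NA_real_, ci_high = NA_real_, p = NA_real_)
    } else {
      nm <- qnames[q - 1]
      if (!nm %in% rownames(cf)) {
        data.frame(quartile = q, n = nq, events = ev, or = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, p = NA_real_)
      } else {
        b <- cf[nm, "Estimate"]; se <- cf[nm, "Std. Error"]
        data.frame(quartile = as.integer(q), n = nq, events = ev,
                   or = exp(b), ci_low = exp(b - 1.96 * se),
                   ci_high = exp(b + 1.96 * se),
                   p = cf[nm, "Pr(>|z|)"])
      }
    }
  })

  out <- list(
    outcome = outcome, tier = tier, covariates = covs,
    quartiles = do.call(rbind, rows),
    p_trend = p_for_trend(data, outcome, tier),
    n_used = nrow(d), n_dropped = sum(!keep),
    converged = fit$converged, separation = res$separation,
    loglik = as.numeric(stats::logLik(fit))
  )
  class(out) <- "lgi_model_report"
  out
}

#' @export
print.lgi_model_report <- function(x, ...) {
  cat(sprintf("Quartile logistic model: %s (%s)\n", x$outcome, x$tier))
  cat(sprintf("  n = %d (%d dropped)%s\n", x$n_used, x$n_dropped,
              if (x$separation) "  [separation/convergence flag]" else ""))
  q <- x$quartiles
  for (i in seq_len(nrow(q))) {
    if (q$quartile[i] == 1) {
      cat(sprintf("  Q1: reference (n=%d, events=%d)\n", q$n[i], q$events[i]))
    } else {
      cat(sprintf("  Q%d: OR %.2f (%.2f, %.2f)  n=%d events=%d\n",
                  q$quartile[i], q$or[i], q$ci_low[i], q$ci_high[i],
                  q$n[i], q$events[i]))
    }
  }
  cat(sprintf("  p for trend: %.4g\n", x$p_trend))
  invisible(x)
}

#' Trend test across ordered LGI quartiles
#'
#' Re-fits the tier's logistic model with the quartile index entered as a
#' single ordinal covariate (1, 2, 3, 4) in place of the indicator terms and
#' returns the Wald p-value of that term — a one-degree-of-freedom test of
#' monotone dose-response.
#'
#' @inheritParams fit_quartile_logistic
#' @return Two-sided p-value.
#' @export
p_for_trend <- function(data, outcome, tier = "crude") {
  covs <- model_covariates(outcome, tier)
  cols <- c(outcome, "lgi_quartile", covs)
  d <- data[.complete_rows(data, cols), cols, drop = FALSE]
  .check_binary_outcome(d[[outcome]], outcome)
  d$q_ord <- as.numeric(d$lgi_quartile)
  rhs <- paste(c("q_ord", covs), collapse = " + ")
  res <- .fit_glm(stats::as.formula(paste(outcome, "~", rhs)), d)
  cf <- summary(res$fit)$coefficients
  unname(cf["q_ord", "Pr(>|z|)"])
}

#' Spearman correlation between the LGI score and the NIHSS score
#'
#' Rank correlation with mid-ranks for ties, two-sided p-value.
#'
#' @param lgi_scores,nihss_values Paired numeric vectors, n >= 3.
#' @return List with `rho`, `p` and `n`. A constant vector leaves `rho`
#'   undefined (`NA`) with a warning.
#' @examples
#' spearman_lgi_nihss(1:10, (1:10)^2)  # rho = 1
#' @export
spearman_lgi_nihss <- function(lgi_scores, nihss_values) {
  ok <- stats::complete.cases(lgi_scores, nihss_values)
  x <- lgi_scores[ok]; y <- nihss_values[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Stratified quartile analysis with interaction tests
#'
#' For each stratifying variable, fits the crude quartile model within each
#' stratum and tests effect modification with a one-degree-of-freedom
#' likelihood-ratio test comparing the pooled model with and without a
#' stratifier-by-ordinal-quartile interaction term.
#'
#' Default strata mirror the source analysis: baseline NIHSS <= 5 / > 5,
#' gender, age < 65 / >= 65, smoking, drinking, prior stroke, coronary
#' heart disease, atrial fibrillation, hypertension, diabetes and
#' dyslipidemia.
#'
#' @param data Scored cohort with endpoints and `lgi_quartile`.
#' @param outcome Binary endpoint column (default `"poor_90d"`).
#' @param strata_defs Named list mapping stratifier name to a function of
#'   the data returning a binary (0/1) vector; `NULL` for the defaults.
#' @param tier Adjustment tier for the within-stratum models (default
#'   crude, as in the source tables).
#' @return Object of class `lgi_stratified`: list of per-stratifier
#'   entries, each with `levels` (named list of `lgi_model_report` or
#'   `NULL` for a skipped stratum) and `p_interaction`.
#' @export
stratified_analysis <- function(data, outcome = "poor_90d",
                                strata_defs = NULL, tier = "crude") {
  if (is.null(strata_defs)) {
    strata_defs <- list(
      nihss = function(d) as.integer(d$nihss_baseline > 5),
      gender = function(d) d$male,
      age = function(d) as.integer(d$age >= 65),
      smoking = function(d) d$smoking,
      drinking = function(d) d$drinking,
      prior_stroke = function(d) d$prior_stroke,
      heart_disease = function(d) d$chd,
      af = function(d) d$af,
      hypertension = function(d) d$hypertension,
      diabetes = function(d) d$diabetes,
      dyslipidemia = function(d) d$dyslipidemia
    )
  }
  out <- lapply(names(strata_defs), function(nm) {
    s <- strata_defs[[nm]](data)
    if (identical(as.integer(s), as.integer(data[[outcome]]))) {
      warning(sprintf("stratifier '%s' duplicates the outcome; skipped", nm),
              call. = FALSE)
      return(list(stratifier = nm, levels = list(), p_interaction = NA_real_,
                  flag = "duplicates_outcome"))
    }
    levels_out <- lapply(c(`0` = 0L, `1` = 1L), function(lev) {
      d <- data[!is.na(s) & s == lev, , drop = FALSE]
      res <- tryCatch(fit_quartile_logistic(d, outcome, tier),
                      error = function(e) NULL)
      if (is.null(res)) {
        warning(sprintf("stratum %s=%d skipped (%s)", nm, lev,
                        "empty or degenerate cells"), call. = FALSE)
      }
      res
    })
    # pooled LRT: outcome ~ ord quartile * stratifier vs additive model
    d <- data[!is.na(s), , drop = FALSE]
    d$q_ord <- as.numeric(d$lgi_quartile)
    d$strat <- s[!is.na(s)]
    keep <- stats::complete.cases(d[, c(outcome, "q_ord", "strat")])
    d <- d[keep, , drop = FALSE]
    p_int <- tryCatch({
      f0 <- stats::glm(stats::as.formula(paste(outcome, "~ q_ord + strat")),
                       data = d, family = stats::binomial())
      f1 <- stats::glm(stats::as.formula(paste(outcome, "~ q_ord * strat")),
                       data = d, family = stats::binomial())
      stats::anova(f0, f1, test = "LRT")$`Pr(>Chi)`[2]
    }, error = function(e) NA_real_)
    list(stratifier = nm, levels = levels_out, p_interaction = p_int,
         flag = NA_character_)
  })
  names(out) <- names(strata_defs)
  class(out) <- "lgi_stratified"
  out
}

#' @export
print.lgi_stratified <- function(x, ...) {
  cat("Stratified quartile analysis\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s p interaction = %s\n", nm,
                format(x[[nm]]$p_interaction, digits = 3)))
  }
  invisible(x)
}
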