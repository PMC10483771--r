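#' ROC area under the curve with DeLong confidence interval
#'
#' The AUC is the Mann-Whitney concordance probability: over all
#' event/nonevent pairs, the proportion where the event's score is higher,
#' counting exact ties as 1/2. The 95% CI uses the DeLong variance from the
#' placement values of each group (the per-subject mean concordance against
#' the other group), truncated to \[0, 1\].
#'
#' @param scores Numeric predictor (risk score or probability); higher
#'   values predict the event.
#' @param outcomes Binary 0/1 (or logical) event indicator; both classes
#'   must be present.
#' @return Object of class `lgi_auc`: list with `auc`, `ci_low`, `ci_high`,
#'   `se`, `n_events`, `n_nonevents`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))  # AUC 1
#' @export
roc_auc <- function(scores, outcomes) {
  ok <- stats::complete.cases(scores, outcomes)
  x <- scores[ok]; y <- as.integer(outcomes[ok])
  if (!all(y %in% c(0L, 1L))) stop("outcomes must be binary 0/1", call. = FALSE)
  ev <- x[y == 1L]; ne <- x[y == 0L]
  m <- length(ev); n <- length(ne)
  if (m == 0L || n == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  # placement values: V10[i] = mean_j psi(ev_i, ne_j), psi = 1/0.5/0
  psi_sum <- function(a, b) {
    # for each element of a: count of b below it plus half the ties
    vapply(a, function(v) sum(b < v) + 0.5 * sum(b == v), numeric(1))
  }
  v10 <- psi_sum(ev, ne) / n
  v01 <- 1 - psi_sum(ne, ev) / m
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z975 <- stats::qnorm(0.975)
  out <- list(auc = auc,
              ci_low = max(0, auc - z975 * se),
              ci_high = min(1, auc + z975 * se),
              se = se, n_events = m, n_nonevents = n)
  class(out) <- "lgi_auc"
  out
}

#' @export
print.lgi_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d events / %d nonevents\n",
              x$auc, x$ci_low, x$ci_high, x$n_events, x$n_nonevents))
  invisible(x)
}

#' ROC curve coordinates
#'
#' Sensitivity and specificity at every distinct threshold, for plotting or
#' CSV export.
#'
#' @inheritParams roc_auc
#' @return Data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, outcomes) {
  ok <- stats::complete.cases(scores, outcomes)
  x <- scores[ok]; y <- as.integer(outcomes[ok])
  thr <- c(-Inf, sort(unique(x)), Inf)
  m <- sum(y == 1L); n <- sum(y == 0L)
  if (m == 0L || n == 0L) stop("both classes must be present", call. = FALSE)
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) sum(x >= t & y == 1L) / m,
                         numeric(1)),
    specificity = vapply(thr, function(t) sum(x < t & y == 0L) / n,
                         numeric(1))
  )
}

.check_risk_pairs <- function(p_old, p_new, outcomes) {
  ok <- stats::complete.cases(p_old, p_new, outcomes)
  y <- as.integer(outcomes[ok])
  if (!all(y %in% c(0L, 1L))) stop("outcomes must be binary 0/1", call. = FALSE)
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop("need both events and nonevents", call. = FALSE)
  }
  if (any(p_old[ok] <= 0 | p_old[ok] >= 1 | p_new[ok] <= 0 | p_new[ok] >= 1)) {
    stop("predicted risks must lie strictly in (0, 1)", call. = FALSE)
  }
  list(po = p_old[ok], pn = p_new[ok], y = y)
}

#' Continuous net reclassification improvement (NRI)
#'
#' NRI = \[P(up | event) - P(down | event)\] +
#' \[P(down | nonevent) - P(up | nonevent)\], where "up"/"down" means the new
#' model's predicted risk is higher/lower than the old model's; exact ties
#' move neither way. Range -2 to 2. The p-value uses the asymptotic normal
#' variance of the two net proportions.
#'
#' @param p_old,p_new Predicted risks in (0, 1) from the baseline and the
#'   augmented model, paired with `outcomes`.
#' @param outcomes Binary 0/1 event indicator.
#' @return List with `nri`, `nri_events`, `nri_nonevents`, `se`, `z`, `p`.
#' @examples
#' continuous_nri(c(0.2, 0.3, 0.1), c(0.4, 0.5, 0.05), c(1, 1, 0))
#' @export
continuous_nri <- function(p_old, p_new, outcomes) {
  d <- .check_risk_pairs(p_old, p_new, outcomes)
  up <- d$pn > d$po; down <- d$pn < d$po
  e <- d$y == 1L; ne <- !e
  n_e <- sum(e); n_ne <- sum(ne)
  up_e <- mean(up[e]); down_e <- mean(down[e])
  up_ne <- mean(up[ne]); down_ne <- mean(down[ne])
  nri_e <- up_e - down_e
  nri_ne <- down_ne - up_ne
  nri <- nri_e + nri_ne
  # variance of a difference of dependent multinomial proportions per group
  var_e <- (up_e + down_e - (up_e - down_e)^2) / n_e
  var_ne <- (up_ne + down_ne - (down_ne - up_ne)^2) / n_ne
  se <- sqrt(var_e + var_ne)
  z <- if (se > 0) nri / se else NA_real_
  list(nri = nri, nri_events = nri_e, nri_nonevents = nri_ne,
       se = se, z = z,
       p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)))
}

#' Integrated discrimination improvement (IDI)
#'
#' IDI is the change in discrimination slope between two risk models:
#' \[mean(p_new | event) - mean(p_new | nonevent)\] -
#' \[mean(p_old | event) - mean(p_old | nonevent)\]. The p-value is the
#' asymptotic two-sample test on the per-subject risk differences
#' `p_new - p_old` between events and nonevents.
#'
#' @inheritParams continuous_nri
#' @return List with `idi`, `slope_old`, `slope_new`, `se`, `z`, `p`.
#' @export
idi <- function(p_old, p_new, outcomes) {
  d <- .check_risk_pairs(p_old, p_new, outcomes)
  e <- d$y == 1L; ne <- !e
  slope_old <- mean(d$po[e]) - mean(d$po[ne])
  slope_new <- mean(d$pn[e]) - mean(d$pn[ne])
  idi_val <- slope_new - slope_old
  diff <- d$pn - d$po
  se <- sqrt(stats::var(diff[e]) / sum(e) + stats::var(diff[ne]) / sum(ne))
  z <- if (se > 0) idi_val / se else NA_real_
  list(idi = idi_val, slope_old = slope_old, slope_new = slope_new,
       se = se, z = z,
       p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)))
}

#' Compare the conventional and LGI add-on prognostic models
#'
#' Fits two in-sample logistic models for the binary endpoint (default the
#' poor 90-day outcome): the conventional model with age and baseline NIHSS,
#' and the add-on model which also includes the LGI score (continuous by
#' default, quartile-coded with `lgi_as_quartile = TRUE`). Reports the raw
#' LGI score's own AUC, both model AUCs with DeLong CIs, the C-statistic
#' difference, and the continuous NRI and IDI between the two sets of
#' in-sample predicted risks.
#'
#' @param data Scored cohort with columns `age`, `nihss_baseline`,
#'   `lgi_score` (and `lgi_quartile` if quartile coding is requested) and
#'   the outcome.
#' @param outcome Binary endpoint column name.
#' @param lgi_as_quartile Code the score as quartile indicators instead of
#'   a continuous covariate.
#' @return Object of class `lgi_discrimination`: list with `auc_lgi`,
#'   `auc_conventional`, `auc_addon` (each an `lgi_auc`),
#'   `c_statistic_delta`, `nri` and `idi` blocks, `n_used`, and a
#'   `converged` flag.
#' @examples
#' cohort <- add_endpoints(simulate_cohort(cohort_config(n_patients = 300,
#'   seed = 9)))
#' sc <- compute_lgi_scores(cohort)
#' cohort$lgi_score <- sc$lgi_score; cohort$lgi_quartile <- sc$lgi_quartile
#' compare_models(cohort)
#' @export
compare_models <- function(data, outcome = "poor_90d",
                           lgi_as_quartile = FALSE) {
  lgi_term <- if (lgi_as_quartile) "factor(lgi_quartile)" else "lgi_score"
  lgi_col <- if (lgi_as_quartile) "lgi_quartile" else "lgi_score"
  cols <- c(outcome, "age", "nihss_baseline", lgi_col)
  keep <- stats::complete.cases(data[, cols])
  d <- data[keep, , drop = FALSE]
  .check_binary_outcome(d[[outcome]], outcome)

  conv <- .fit_glm(stats::as.formula(paste(outcome, "~ age + nihss_baseline")), d)
  addon <- .fit_glm(stats::as.formula(
    paste(outcome, "~ age + nihss_baseline +", lgi_term)), d)
  p_old <- stats::fitted(conv$fit)
  p_new <- stats::fitted(addon$fit)
  y <- d[[outcome]]

  auc_conv <- roc_auc(p_old, y)
  auc_addon <- roc_auc(p_new, y)
  out <- list(
    outcome = outcome,
    auc_lgi = roc_auc(d$lgi_score, y),
    auc_conventional = auc_conv,
    auc_addon = auc_addon,
    c_statistic_delta = auc_addon$auc - auc_conv$auc,
    nri = continuous_nri(p_old, p_new, y),
    idi = idi(p_old, p_new, y),
    n_used = nrow(d), n_dropped = sum(!keep),
    converged = conv$fit$converged && addon$fit$converged,
    separation = conv$separation || addon$separation
  )
  class(out) <- "lgi_discrimination"
  out
}

#' @export
print.lgi_discrimination <- function(x, ...) {
  cat(sprintf("Added predictive value of the LGI score for '%s' (n = %d)\n",
              x$outcome, x$n_used))
  cat(sprintf("  AUC, LGI score alone:   %.3f (%.3f-%.3f)\n",
              x$auc_lgi$auc, x$auc_lgi$ci_low, x$auc_lgi$ci_high))
  cat(sprintf("  AUC, conventional:      %.3f (%.3f-%.3f)\n",
              x$auc_conventional$auc, x$auc_conventional$ci_low,
              x$auc_conventional$ci_high))
  cat(sprintf("  AUC, add-on:            %.3f (%.3f-%.3f)\n",
              x$auc_addon$auc, x$auc_addon$ci_low, x$auc_addon$ci_high))
  cat(sprintf("  delta C-statistic:      %.4f\n", x$c_statistic_delta))
  cat(sprintf("  continuous NRI:         %.1f%% (p = %.3g)\n",
              100 * x$nri$nri, x$nri$p))
  cat(sprintf("  IDI:                    %.2f%% (p = %.3g)\n",
              100 * x$idi$idi, x$idi$p))
  invisible(x)
}
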