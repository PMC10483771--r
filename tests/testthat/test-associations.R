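test_that("covariate tiers resolve per the adjustment scheme", {
  expect_length(model_covariates("poor_90d", "crude"), 0)
  expect_equal(model_covariates("end_flag", "model1"), c("male", "age"))
  m2_sev <- model_covariates("severe_baseline", "model2")
  expect_false("nihss_baseline" %in% m2_sev)
  expect_true("nihss_baseline" %in% model_covariates("poor_90d", "model2"))
  expect_setequal(setdiff(model_covariates("poor_90d", "model2"),
                          c(m2_sev, "nihss_baseline")), character(0))
})

test_that("crude Q4-vs-Q1 odds ratio matches the closed-form 2x2 oracle", {
  co <- scored_cohort(n = 800, seed = 23)
  sub <- co[co$lgi_quartile %in% c(1, 4), ]
  sub$lgi_quartile <- ifelse(sub$lgi_quartile == 4, 2L, 1L)
  # force factor levels 1,2 so "quartile 2" is the Q4 indicator
  rep <- fit_quartile_logistic(sub, "poor_90d", "crude")
  a <- sum(sub$poor_90d == 1 & sub$lgi_quartile == 2)
  b <- sum(sub$poor_90d == 0 & sub$lgi_quartile == 2)
  c_ <- sum(sub$poor_90d == 1 & sub$lgi_quartile == 1)
  d <- sum(sub$poor_90d == 0 & sub$lgi_quartile == 1)
  or_2x2 <- (a * d) / (b * c_)
  or_fit <- rep$quartiles$or[rep$quartiles$quartile == 2]
  expect_equal(or_fit, or_2x2, tolerance = 1e-6)
})

test_that("every collapsed quartile pair reproduces its 2x2 odds ratio", {
  co <- scored_cohort(n = 600, seed = 29)
  for (q in 2:4) {
    sub <- co[co$lgi_quartile %in% c(1, q), ]
    sub$lgi_quartile <- ifelse(sub$lgi_quartile == q, 2L, 1L)
    rep <- fit_quartile_logistic(sub, "poor_90d", "crude")
    tab <- table(sub$lgi_quartile, sub$poor_90d)
    or_2x2 <- (tab["2", "1"] * tab["1", "0"]) /
              (tab["2", "0"] * tab["1", "1"])
    expect_equal(rep$quartiles$or[rep$quartiles$quartile == 2], or_2x2,
                 tolerance = 1e-6)
  }
})

test_that("model report invariants hold across tiers", {
  co <- scored_cohort(n = 800, seed = 37)
  lls <- sapply(c("crude", "model1", "model2"), function(tier) {
    rep <- fit_quartile_logistic(co, "poor_90d", tier)
    expect_equal(rep$quartiles$or[1], 1)
    ok <- rep$quartiles$quartile > 1
    expect_true(all(rep$quartiles$ci_low[ok] <= rep$quartiles$or[ok]))
    expect_true(all(rep$quartiles$or[ok] <= rep$quartiles$ci_high[ok]))
    expect_equal(rep$n_used + rep$n_dropped, nrow(co))
    rep$loglik
  })
  # nested models: richer tiers cannot lose likelihood on the same rows
  expect_true(lls["model1"] >= lls["crude"])
  expect_true(lls["model2"] >= lls["model1"])
})

test_that("degenerate outcomes and separation are flagged, not silent", {
  co <- scored_cohort(n = 100, seed = 43)
  co$const <- 1L
  expect_error(fit_quartile_logistic(co, "const", "crude"), "single class")
  expect_error(p_for_trend(co, "const"), "single class")
  co$sep <- as.integer(co$lgi_quartile == 4)
  rep <- fit_quartile_logistic(co, "sep", "crude")
  expect_true(rep$separation)
})

test_that("Spearman correlation handles monotone, reversed and constant input", {
  expect_equal(spearman_lgi_nihss(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_lgi_nihss(1:10, -(1:10))$rho, -1)
  expect_warning(res <- spearman_lgi_nihss(rep(2, 10), 1:10), "constant")
  expect_true(is.na(res$rho))
  set.seed(61)
  x <- rnorm(2000); y <- rnorm(2000)
  expect_lt(abs(spearman_lgi_nihss(x, y)$rho), 3 / sqrt(2000))
})

test_that("stratified analysis: symmetry, skipping and outcome duplication", {
  co <- scored_cohort(n = 600, seed = 47)
  # two identical strata -> identical within-stratum ORs
  co$dup <- rep(c(0L, 1L), length.out = nrow(co))
  half <- co[co$dup == 0, ]
  co2 <- rbind(half, transform(half, dup = 1L, id = paste0(id, "b")))
  res <- stratified_analysis(co2, "poor_90d",
                             strata_defs = list(dup = function(d) d$dup))
  expect_equal(res$dup$levels[["0"]]$quartiles$or,
               res$dup$levels[["1"]]$quartiles$or, tolerance = 1e-8)

  expect_warning(
    res2 <- stratified_analysis(co, "poor_90d",
      strata_defs = list(self = function(d) d$poor_90d)),
    "duplicates the outcome")
  expect_true(is.na(res2$self$p_interaction))
})

test_that("default stratifiers produce reports with interaction p-values", {
  co <- scored_cohort(n = 800, seed = 53)
  res <- suppressWarnings(stratified_analysis(co, "poor_90d"))
  expect_named(res, c("nihss", "gender", "age", "smoking", "drinking",
                      "prior_stroke", "heart_disease", "af", "hypertension",
                      "diabetes", "dyslipidemia"))
  ps <- vapply(res, function(s) s$p_interaction, numeric(1))
  expect_true(all(is.na(ps) | (ps >= 0 & ps <= 1)))
  expect_true(sum(!is.na(ps)) >= 9)
})
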