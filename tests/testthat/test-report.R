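test_that("EPV sample-size rule reproduces the published worked examples", {
  expect_identical(epv_sample_size(15, 10, 0.8), 187.5)
  expect_identical(epv_sample_size(15, 20, 0.8), 375)
  expect_equal(epv_sample_size(10, 10, 1.0), 100)
  expect_error(epv_sample_size(15, 10, 0), "event_proportion")
})

test_that("chi-square on the shipped subtype-by-quartile counts matches hand arithmetic", {
  m <- subtype_quartile_counts()
  expect_equal(sum(m), 876)
  # independent computation from first principles
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  stat_hand <- sum((m - expected)^2 / expected)
  stat_pkg <- stats::chisq.test(m, correct = FALSE)$statistic
  expect_equal(unname(stat_pkg), stat_hand, tolerance = 1e-10)
  expect_equal(stat_hand, 25.8015546502, tolerance = 1e-8)
})

test_that("descriptive table reproduces the published subtype comparison", {
  m <- subtype_quartile_counts()
  # expand the contingency table back to patient-level rows
  long <- do.call(rbind, lapply(rownames(m), function(st)
    do.call(rbind, lapply(1:4, function(q)
      if (m[st, q] > 0)
        data.frame(toast_subtype = st, lgi_quartile = q)[rep(1, m[st, q]), ]
      else NULL))))
  t1 <- build_descriptive_table(long, "lgi_quartile", "toast_subtype")
  expect_equal(t1$test, "chisq")
  expect_equal(t1$p, pchisq(25.8015546502, 9, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("test gating: identical proportions, sparse cells, skew", {
  d <- data.frame(g = rep(1:2, each = 40), flag = rep(c(0, 1), 40))
  t1 <- build_descriptive_table(d, "g", "flag")
  expect_equal(t1$p, 1)  # identical proportions across groups

  sparse <- data.frame(g = rep(1:2, each = 6), flag = c(rep(0, 5), 1,
                                                        rep(0, 4), 1, 1))
  t2 <- build_descriptive_table(sparse, "g", "flag")
  expect_equal(t2$test, "fisher")  # expected cells < 5

  set.seed(1)
  d3 <- data.frame(g = rep(1:4, each = 60),
                   norm = rnorm(240, 10),
                   skew = rexp(240))
  t3 <- build_descriptive_table(d3, "g", c("norm", "skew"))
  expect_equal(t3$test[t3$variable == "norm"], "anova")
  expect_match(t3[t3$variable == "norm", "group_1"], "±")
  expect_equal(t3$test[t3$variable == "skew"], "kruskal")
  expect_match(t3[t3$variable == "skew", "group_1"], "\\[")

  d3$empty <- NA_real_
  expect_warning(build_descriptive_table(d3, "g", c("norm", "empty")),
                 "entirely missing")
})

test_that("descriptive counts equal direct tabulation of the scored cohort", {
  co <- scored_cohort(n = 300, seed = 13)
  t1 <- build_descriptive_table(co, "lgi_quartile", c("male", "toast_subtype"))
  male_q1 <- sum(co$male[co$lgi_quartile == 1])
  expect_match(t1[t1$variable == "male", "group_1"],
               paste0("^", male_q1, " \\("))
})

test_that("pipeline writes a complete, deterministic report bundle", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- cohort_config(n_patients = 250, seed = 5)
  res <- suppressWarnings(run_pipeline(config = cfg, out_dir = out1))
  report_files <- c("table1_descriptive.csv", "severity_end_models.json",
                    "poor_outcome_models.json", "stratified_models.json",
                    "discrimination.json")
  for (f in report_files) expect_true(file.exists(file.path(out1, f)))
  expect_true(file.exists(file.path(out1, "cohort_scored.csv")))
  expect_true(file.exists(file.path(out1, "pipeline_log.json")))

  # exclusion accounting: rows_in = analyzed + excluded at every stage
  log <- jsonlite::read_json(file.path(out1, "pipeline_log.json"))
  for (st in log$stages) {
    expect_equal(st$rows_in, st$rows_analyzed + st$rows_excluded)
  }

  suppressWarnings(run_pipeline(config = cfg, out_dir = out2))
  for (f in c(report_files, "pipeline_log.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("pipeline aborts cleanly below the decile minimum", {
  expect_error(
    run_pipeline(config = cohort_config(n_patients = 5, seed = 1),
                 out_dir = withr::local_tempdir()),
    "at least 10")
})
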