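test_that("AUC equals exhaustive pairwise concordance", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(20:100, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    x <- round(rnorm(n, mean = y), 1)  # rounding induces ties
    expect_equal(roc_auc(x, y)$auc, brute_auc(x, y), tolerance = 1e-10)
  }
})

test_that("AUC endpoints: perfect separation gives 1, all ties give 0.5", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(2.5, 30), rep(0:1, 15))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  y <- rbinom(200, 1, 0.3)
  x <- rnorm(200, mean = 0.8 * y)
  ours <- roc_auc(x, y)
  ref <- pROC::roc(y, x, quiet = TRUE, direction = "<")
  ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  expect_equal(ours$ci_low, ci[1], tolerance = 1e-6)
  expect_equal(ours$ci_high, ci[3], tolerance = 1e-6)
})

test_that("continuous NRI matches the direct-counting oracle", {
  # 5 events moving up,up,down,tie,up; 3 nonevents moving down,up,down
  p_old <- c(0.2, 0.2, 0.5, 0.4, 0.1, 0.3, 0.3, 0.6)
  p_new <- c(0.3, 0.4, 0.3, 0.4, 0.2, 0.2, 0.5, 0.4)
  y <- c(1, 1, 1, 1, 1, 0, 0, 0)
  res <- continuous_nri(p_old, p_new, y)
  expect_equal(res$nri, (3 / 5 - 1 / 5) + (2 / 3 - 1 / 3), tolerance = 1e-12)
})

test_that("NRI is zero under identical risks and 2 under perfect movement", {
  p <- runif(40, 0.05, 0.95)
  y <- rep(0:1, 20)
  expect_equal(continuous_nri(p, p, y)$nri, 0)
  p_new <- ifelse(y == 1, pmin(p + 0.01, 0.99), pmax(p - 0.01, 0.01))
  expect_equal(continuous_nri(p, p_new, y)$nri, 2)
})

test_that("IDI matches hand arithmetic and definitional slope change", {
  p_old <- c(0.10, 0.20, 0.30, 0.40, 0.50, 0.15, 0.25, 0.35, 0.45, 0.05)
  p_new <- c(0.20, 0.25, 0.45, 0.50, 0.55, 0.10, 0.20, 0.30, 0.40, 0.04)
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  slope_old <- mean(p_old[y == 1]) - mean(p_old[y == 0])
  slope_new <- mean(p_new[y == 1]) - mean(p_new[y == 0])
  res <- idi(p_old, p_new, y)
  expect_equal(res$idi, slope_new - slope_old, tolerance = 1e-12)
  expect_equal(res$slope_old, slope_old)
  expect_equal(idi(p_old, p_old, y)$idi, 0)
})

test_that("NRI and IDI are exactly antisymmetric under model swap", {
  set.seed(79)
  y <- rep(0:1, 25)
  p1 <- runif(50, 0.05, 0.95)
  p2 <- plogis(qlogis(p1) + rnorm(50, 0.3 * (y - 0.5)))
  expect_equal(continuous_nri(p1, p2, y)$nri,
               -continuous_nri(p2, p1, y)$nri, tolerance = 1e-12)
  expect_equal(idi(p1, p2, y)$idi, -idi(p2, p1, y)$idi, tolerance = 1e-12)
})

test_that("label permutation centres NRI and IDI at zero", {
  set.seed(83)
  n <- 150
  y <- rep(0:1, c(100, 50))
  p1 <- runif(n, 0.1, 0.9)
  p2 <- plogis(qlogis(p1) + rnorm(n, sd = 0.3))
  nris <- idis <- numeric(500)
  for (b in 1:500) {
    yp <- sample(y)
    nris[b] <- continuous_nri(p1, p2, yp)$nri
    idis[b] <- idi(p1, p2, yp)$idi
  }
  expect_lt(abs(mean(nris)), 2 * sd(nris) / sqrt(500))
  expect_lt(abs(mean(idis)), 2 * sd(idis) / sqrt(500))
})

test_that("model comparison returns a coherent discrimination report", {
  co <- scored_cohort(n = 600, seed = 89)
  rep <- compare_models(co)
  for (blk in list(rep$auc_lgi, rep$auc_conventional, rep$auc_addon)) {
    expect_true(blk$auc >= 0 && blk$auc <= 1)
    expect_true(blk$ci_low <= blk$auc && blk$auc <= blk$ci_high)
  }
  expect_true(rep$nri$nri >= -2 && rep$nri$nri <= 2)
  expect_true(rep$idi$idi >= -1 && rep$idi$idi <= 1)
  # the add-on model nests the conventional one: in-sample AUC cannot drop
  expect_gte(rep$auc_addon$auc, rep$auc_conventional$auc - 1e-10)
  expect_equal(rep$c_statistic_delta,
               rep$auc_addon$auc - rep$auc_conventional$auc)
  # quartile-coded variant runs and nests too
  repq <- compare_models(co, lgi_as_quartile = TRUE)
  expect_gte(repq$auc_addon$auc, repq$auc_conventional$auc - 1e-10)
})

test_that("a strong generated inflammation effect raises the add-on AUC", {
  wins <- 0L
  for (seed in 1:20) {
    cfg <- cohort_config(n_patients = 500, seed = seed,
      outcome_model = list(
        end = c(intercept = qlogis(0.08), inflammation = 0.5),
        poor_90d = c(intercept = -2.0, inflammation = 1.2,
                     age = 0.04, nihss = 0.25)))
    co <- add_endpoints(simulate_cohort(cfg))
    sc <- compute_lgi_scores(co)
    co$lgi_score <- sc$lgi_score
    rep <- compare_models(co)
    if (rep$auc_addon$auc > rep$auc_conventional$auc) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("ROC curve coordinates are monotone and bracket the data", {
  co <- scored_cohort(n = 200, seed = 97)
  rc <- roc_curve(co$lgi_score, co$poor_90d)
  expect_true(all(diff(rc$sensitivity) <= 0))
  expect_true(all(diff(rc$specificity) >= 0))
  expect_equal(rc$sensitivity[1], 1)
  expect_equal(rc$specificity[1], 0)
})
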