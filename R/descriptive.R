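#' Events-per-variable sample-size rule for logistic regression
#'
#' Required sample size under the events-per-variable (EPV) rule of thumb:
#' `n_factors * epv / event_proportion`. With 15 candidate factors, an EPV
#' of 10 and an anticipated event proportion of 0.8 this gives 187.5; with
#' EPV 20 it gives 375.
#'
#' @param n_factors Number of candidate predictors (>= 1).
#' @param epv Events per variable, typically 10-20.
#' @param event_proportion Anticipated event proportion in (0, 1\].
#' @return Required sample size, unrounded (callers may `ceiling()`).
#' @examples
#' epv_sample_size(15, 10, 0.8)  # 187.5
#' @export
epv_sample_size <- function(n_factors, epv, event_proportion) {
  if (n_factors < 1) stop("n_factors must be >= 1", call. = FALSE)
  if (epv < 1) stop("epv must be >= 1", call. = FALSE)
  if (event_proportion <= 0 || event_proportion > 1) {
    stop("event_proportion must lie in (0, 1]", call. = FALSE)
  }
  n_factors * epv / event_proportion
}

#' Published stroke-subtype by score-quartile contingency counts
#'
#' The 4x4 table of TOAST subtype counts (rows LAA, CE, SAA, Other) across
#' LGI score quartiles (columns Q1-Q4) from the 876-patient study cohort,
#' shipped as a plain-text fixture for the descriptive-table machinery.
#'
#' @return Integer matrix with subtype rows and quartile columns.
#' @export
subtype_quartile_counts <- function() {
  path <- system.file("extdata", "subtype_quartile_counts.csv",
                      package = "lgiscore")
  d <- utils::read.csv(path, row.names = 1)
  m <- as.matrix(d)
  colnames(m) <- paste0("Q", 1:4)
  storage.mode(m) <- "integer"
  m
}

.is_categorical <- function(v) {
  is.character(v) || is.factor(v) || is.logical(v) ||
    all(stats::na.omit(v) %in% c(0, 1))
}

.fmt_mean_sd <- function(v) sprintf("%.1f ± %.1f", mean(v), stats::sd(v))
.fmt_median_iqr <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.1f [%.1f, %.1f]", q[2], q[1], q[3])
}

.categorical_row <- function(v, g) {
  tab <- table(v, g)
  if (nrow(tab) < 2) {
    return(list(test = "none", p = NA_real_,
                summaries = vapply(colnames(tab), function(cn)
                  sprintf("%d (100%%)", sum(g == cn, na.rm = TRUE)),
                  character(1))))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- any(expected < 5)
  res <- if (use_fisher) {
    p <- tryCatch(stats::fisher.test(tab)$p.value,
                  error = function(e)
                    stats::fisher.test(tab, simulate.p.value = TRUE,
                                       B = 1e4)$p.value)
    list(test = "fisher", p = p)
  } else {
    list(test = "chisq",
         p = stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  # summarize the "positive" level for binary flags, all levels otherwise
  lev <- rownames(tab)
  show_lev <- if (identical(sort(lev), c("0", "1"))) "1" else lev
  summaries <- vapply(colnames(tab), function(cn) {
    ntot <- sum(tab[, cn])
    paste(vapply(show_lev, function(l)
      sprintf("%d (%.1f%%)", tab[l, cn], 100 * tab[l, cn] / ntot),
      character(1)), collapse = "; ")
  }, character(1))
  c(res, list(summaries = summaries))
}

.continuous_row <- function(v, g, alpha = 0.05) {
  groups <- split(v, g)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  k <- length(groups)
  # Lilliefors-corrected KS normality per group (needs n >= 5 and spread)
  normal <- all(vapply(groups, function(x) {
    if (length(x) < 5 || stats::sd(x) == 0) return(FALSE)
    nortest::lillie.test(x)$p.value > alpha
  }, logical(1)))
  gf <- factor(g)
  equal_var <- if (normal) {
    lev <- car::leveneTest(v ~ gf)
    lev[["Pr(>F)"]][1] > alpha
  } else FALSE
  parametric <- normal && equal_var
  if (parametric) {
    p <- if (k == 2) stats::t.test(v ~ gf, var.equal = TRUE)$p.value
         else summary(stats::aov(v ~ gf))[[1]][["Pr(>F)"]][1]
    test <- if (k == 2) "t" else "anova"
    fmt <- .fmt_mean_sd
  } else {
    p <- if (k == 2) stats::wilcox.test(v ~ gf, exact = FALSE)$p.value
         else stats::kruskal.test(v, gf)$p.value
    test <- if (k == 2) "wilcoxon" else "kruskal"
    fmt <- .fmt_median_iqr
  }
  list(test = test, p = p, normal = normal, equal_var = equal_var,
       summaries = vapply(groups, fmt, character(1)))
}

#' Baseline characteristics table by group
#'
#' Builds a descriptive table in the style of a clinical "Table 1".
#' Categorical variables are summarized as count (percent) and compared
#' with the chi-square test, switching to Fisher's exact test whenever any
#' expected cell count falls below 5. Continuous variables are gated per
#' variable: Lilliefors-corrected Kolmogorov-Smirnov normality in every
#' group and Levene's equal-variance test (both at alpha = 0.05) select
#' ANOVA/t-test with mean +- SD display, otherwise Kruskal-Wallis /
#' Mann-Whitney with median \[IQR\].
#'
#' @param data Data frame.
#' @param group_col Name of the grouping column (>= 2 levels).
#' @param vars Variables to summarize; default every column except the
#'   grouping column and `id`.
#' @return `data.frame` of class `lgi_table1`: one row per variable with
#'   `variable`, `type`, per-group summary columns, `test` and `p`.
#'   All-missing variables are skipped with a warning.
#' @export
build_descriptive_table <- function(data, group_col, vars = NULL) {
  if (!group_col %in% names(data)) {
    stop("grouping column '", group_col, "' not found", call. = FALSE)
  }
  g <- data[[group_col]]
  if (length(unique(stats::na.omit(g))) < 2) {
    stop("grouping column needs at least 2 levels", call. = FALSE)
  }
  if (is.null(vars)) vars <- setdiff(names(data), c(group_col, "id"))
  glev <- sort(unique(stats::na.omit(g)))

  rows <- lapply(vars, function(vn) {
    v <- data[[vn]]
    ok <- !is.na(v) & !is.na(g)
    if (!any(ok)) {
      warning("variable '", vn, "' is entirely missing; skipped",
              call. = FALSE)
      return(NULL)
    }
    vv <- v[ok]; gg <- factor(g[ok], levels = glev)
    if (.is_categorical(vv)) {
      res <- .categorical_row(vv, gg)
      type <- "categorical"
    } else {
      res <- .continuous_row(vv, gg)
      type <- "continuous"
    }
    summ <- res$summaries[as.character(glev)]
    names(summ) <- paste0("group_", glev)
    cbind(data.frame(variable = vn, type = type, stringsAsFactors = FALSE),
          as.data.frame(as.list(summ), stringsAsFactors = FALSE,
                        optional = TRUE),
          data.frame(test = res$test, p = res$p))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lgi_table1", "data.frame")
  out
}

#' @export
print.lgi_table1 <- function(x, ...) {
  cat(sprintf("Baseline characteristics (%d variables)\n", nrow(x)))
  print.data.frame(x, right = FALSE)
  invisible(x)
}
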