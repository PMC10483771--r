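# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# mid-rank decile by direct counting: r_i = #(x < x_i) + (#(x == x_i)+1)/2
brute_deciles <- function(x) {
  n <- length(x)
  vapply(x, function(v) {
    r <- sum(x < v) + (sum(x == v) + 1) / 2
    ceiling(10 * r / n)
  }, numeric(1))
}

# AUC by exhaustive event x nonevent pair counting, ties as 1/2
brute_auc <- function(scores, outcomes) {
  ev <- scores[outcomes == 1]
  ne <- scores[outcomes == 0]
  total <- 0
  for (a in ev) for (b in ne) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(ev) * length(ne))
}

# small default cohort reused by several tests
small_cohort <- function(n = 120, seed = 7, ...) {
  simulate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}

scored_cohort <- function(n = 400, seed = 7, ...) {
  co <- small_cohort(n, seed, ...)
  sc <- compute_lgi_scores(co)
  co$nlr <- sc$nlr
  co$lgi_score <- sc$lgi_score
  co$lgi_quartile <- sc$lgi_quartile
  add_endpoints(co)
}

# null-configured generator: no inflammation signal anywhere
null_config <- function(n, seed) {
  cohort_config(
    n_patients = n, seed = seed,
    inflammation_loading = c(crp = 0, wbc = 0, neut = 0, lymph = 0, plt = 0),
    outcome_model = list(
      end = c(intercept = stats::qlogis(0.08), inflammation = 0),
      poor_90d = c(intercept = -2.0, inflammation = 0, age = 0, nihss = 0)
    ),
    nihss_baseline_dist = list(size = 1.3, mu = 2.6, inflammation = 0)
  )
}
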