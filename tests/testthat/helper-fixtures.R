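# shared fixtures: simulations are cached per seed so that several test
# files can reuse the same default cohort without regenerating it

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_monitoring_data(seed = seed)
  }
  .sim_cache[[key]]
}

cached_labels <- function(seed) {
  key <- paste0("l", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- label_fatigue(cached_sim(seed))
  }
  .sim_cache[[key]]
}

# a reference athlete at the cohort means, for single-profile operations
mean_profile <- function(n = 1) {
  tibble::tibble(
    athlete_id = sprintf("p%02d", seq_len(n)),
    position = factor(rep("MF", n), levels = c("GK", "DF", "MF", "FW")),
    hr_max = 196.4, hr_rest = 58.2,
    cmj_baseline = 38.6, lnrmssd_baseline = 4.18,
    sprint10_baseline = 1.78, attendance_rate = 0.95,
    wellness_base = 3.95
  )
}

# brute-force pairwise AUC oracle: fraction of positive/negative pairs
# ranked correctly, ties counted one half
auc_pairwise <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# unrolled closed-form EWMA oracle (independent of the recursive code path)
ewma_unrolled <- function(loads, span) {
  lambda <- 2 / (span + 1)
  n <- length(loads)
  vapply(seq_len(n), function(t) {
    if (t == 1) return(loads[1])
    k <- 1:(t - 1)
    lambda * sum((1 - lambda)^(t - 1 - (1:(t - 1))) * loads[2:t]) +
      (1 - lambda)^(t - 1) * loads[1]
  }, numeric(1))
}

# a clean criterion-input row, overridable per test
criterion_row <- function(...) {
  defaults <- tibble::tibble(
    athlete_id = "a1", day_index = 10L,
    cmj_drop = 0, hrv_drop = 0, wellness_total = 20,
    rpe_today = 3, rpe_prev = 3
  )
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  defaults
}
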