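test_that("cohort generation honours the position mix and is reproducible", {
  coh <- generate_cohort(seed = 7)
  expect_equal(nrow(coh), 48)
  expect_equal(as.vector(table(coh$position)[c("GK", "DF", "MF", "FW")]),
               c(3, 15, 18, 12))
  expect_identical(coh, generate_cohort(seed = 7))
  expect_true(all(coh$hr_max > coh$hr_rest))
  expect_true(all(coh$hr_rest > 0))
  expect_true(all(coh$cmj_baseline > 0))
  expect_error(generate_cohort(3, c(GK = 1, DF = 1, MF = 1, FW = 0)),
               "at least 4")
  expect_error(generate_cohort(48, c(GK = 1, DF = 1, MF = 1, FW = 1)), "sum")
})

test_that("cohort marginals converge to the configured targets", {
  coh <- generate_cohort(1000, c(GK = 100, DF = 300, MF = 350, FW = 250),
                         seed = 11)
  expect_lt(abs(mean(coh$hr_max) - 196.4), 1.0)
  expect_lt(abs(mean(coh$hr_rest) - 58.2), 1.0)
  expect_lt(abs(mean(coh$cmj_baseline) - 38.6), 0.5)
})

test_that("calendar layout matches the periodisation", {
  cal <- generate_calendar(12, 24)
  expect_equal(nrow(cal), 84)
  expect_equal(sum(cal$day_type == "match"), 24)
  expect_true(all(cal$phase[cal$week_index <= 4] == "progressive"))
  expect_true(all(cal$phase[cal$week_index %in% 5:10] == "maintenance"))
  expect_true(all(cal$phase[cal$week_index >= 11] == "taper"))
  expect_equal(sum(cal$is_test_day), 12)
  expect_true(all(cal$day_type[cal$is_test_day] == "rest"))

  one <- generate_calendar(1, 0)
  expect_equal(nrow(one), 7)
  expect_equal(sum(one$day_type == "match"), 0)
  expect_error(generate_calendar(2, 15), "exceed")
})

test_that("latent state follows the impulse-response recursion", {
  s0 <- latent_state(0, decay_tau = 5, gain_kappa = 0.8)
  expect_equal(step_latent_state(s0, 0)$fatigue_level, 0)
  expect_equal(step_latent_state(latent_state(10, 5, 0.8), 0)$fatigue_level,
               10 * exp(-0.2), tolerance = 1e-10)
  expect_equal(step_latent_state(s0, 300)$fatigue_level, 2.4)
  expect_error(step_latent_state(s0, -5), "non-negative")
  # strictly decreasing over consecutive zero-load days, never negative
  s <- latent_state(6, 5, 0.8)
  prev <- s$fatigue_level
  for (i in 1:10) {
    s <- step_latent_state(s, 0)
    expect_lt(s$fatigue_level, prev)
    expect_gte(s$fatigue_level, 0)
    prev <- s$fatigue_level
  }
})

test_that("session marginals land on the configured training/match targets", {
  prof <- mean_profile(1000)
  tr <- simulate_session(prof, "training", latent_state(5.4), seed = 3,
                         f_ref = 5.4)
  ma <- simulate_session(prof, "match", latent_state(5.4), seed = 4,
                         f_ref = 5.4)
  expect_lt(abs(mean(tr$total_distance) - 5765), 150)
  expect_lt(abs(mean(ma$player_load) - 892), 25)
  expect_lt(abs(mean(ma$total_distance) - 9847), 200)
  expect_lt(abs(mean(tr$hr_mean) - 142), 3)
})

test_that("zero-noise sessions sit at the marginal means and satisfy invariants", {
  ses <- simulate_session(mean_profile(5), "training", latent_state(0),
                          seed = 1, noise_scale = 0)
  expect_true(all(ses$hsr_distance >= ses$sprint_distance))
  expect_true(all(ses$hr_peak <= mean_profile(5)$hr_max))
  expect_true(all(ses$total_distance >= ses$hsr_distance))
  expect_error(simulate_session(mean_profile(1), "rest", latent_state(0)),
               "rest")
})

test_that("generated session rows always satisfy the record invariants", {
  for (seed in 1:3) {
    dat <- cached_sim(seed)
    ses <- dplyr::left_join(
      dat$sessions,
      dplyr::select(dat$athletes, athlete_id, hr_rest, hr_max),
      by = "athlete_id"
    )
    ok <- stats::complete.cases(
      ses[, c("hsr_distance", "sprint_distance", "total_distance",
              "hr_mean", "hr_peak", "rpe", "duration",
              paste0("zone", 1:5, "_min"))]
    )
    ses <- ses[ok, ]
    expect_true(all(ses$hsr_distance >= ses$sprint_distance))
    expect_true(all(ses$total_distance >= ses$hsr_distance))
    expect_true(all(ses$hr_mean <= ses$hr_peak + 1e-9))
    expect_true(all(ses$hr_peak <= ses$hr_max + 1e-9))
    expect_true(all(ses$hr_mean > ses$hr_rest))
    expect_true(all(ses$rpe >= 0 & ses$rpe <= 10))
    zone_sum <- rowSums(ses[, paste0("zone", 1:5, "_min")])
    expect_true(all(zone_sum <= ses$duration + 1e-9))
  }
})

test_that("morning records respond to fatigue as configured", {
  prof <- mean_profile(1)
  quiet <- simulate_morning(prof, latent_state(0), seed = 1, noise_scale = 0)
  expect_equal(quiet$lnrmssd, round(prof$lnrmssd_baseline, 3))
  expect_equal(quiet$wellness_total,
               as.integer(5 * round(prof$wellness_base)))
  loaded <- simulate_morning(prof, latent_state(10), seed = 1, noise_scale = 0)
  expect_equal(loaded$lnrmssd, round(prof$lnrmssd_baseline - 0.18 * 10, 3))
  # wellness items stay in range and totals in [5, 25]
  dat <- simulate_morning(mean_profile(500), latent_state(8), seed = 2)
  expect_true(all(dat$wellness_total >= 5 & dat$wellness_total <= 25))
  # rmssd stores exp(lnrmssd) up to output rounding of both columns
  expect_true(all(abs(dat$rmssd - exp(dat$lnrmssd)) < 0.1))
})

test_that("weekly tests decline with fatigue and recover the baseline", {
  prof <- mean_profile(1)
  rest <- simulate_weekly_test(prof, latent_state(0), seed = 1,
                               noise_scale = 0)
  expect_equal(rest$cmj_height, 38.6)
  tired <- simulate_weekly_test(prof, latent_state(6), seed = 1,
                                noise_scale = 0)
  expect_equal(tired$cmj_height, round(38.6 * (1 - 0.02 * 6), 1))
  many <- simulate_weekly_test(mean_profile(500), latent_state(0), seed = 9)
  expect_lt(abs(mean(many$cmj_height) - 38.6), 0.5)
  expect_true(all(many$cmj_height > 0))
})

test_that("missingness mask is MCAR at the configured rate and reproducible", {
  tab <- tibble::tibble(athlete_id = rep("a", 2000),
                        day_index = 1:2000,
                        v1 = rnorm(2000), v2 = rnorm(2000),
                        v3 = rnorm(2000), v4 = rnorm(2000),
                        v5 = rnorm(2000))
  none <- apply_missingness(list(x = tab), list(x = 0), seed = 1)
  expect_identical(none$x, tab)
  m1 <- apply_missingness(list(x = tab), list(x = 0.054), seed = 2)
  n_missing <- sum(is.na(m1$x))
  expect_lt(abs(n_missing - 0.054 * 10000), 50)
  m2 <- apply_missingness(list(x = tab), list(x = 0.054), seed = 2)
  expect_identical(m1, m2)
  expect_error(apply_missingness(list(x = tab), list(x = 1)), "rates")
  # identifier columns never blanked
  expect_false(anyNA(m1$x$athlete_id))
  expect_false(anyNA(m1$x$day_index))
})

test_that("the full generator is byte-deterministic under a fixed seed", {
  a <- simulate_monitoring_data(seed = 42)
  b <- simulate_monitoring_data(seed = 42)
  expect_identical(a, b)
})

test_that("the accelerometer toy trace exercises the Player Load formula", {
  tr <- simulate_accel_trace(seconds = 2, seed = 1)
  expect_equal(nrow(tr), 200)
  pl <- compute_player_load(tr)
  expect_gt(pl, 0)
})
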