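test_that("TRIMP follows the Banister form", {
  expect_equal(compute_trimp(0, 140, 58, 196), 0)
  expect_equal(compute_trimp(60, 58, 58, 196), 0)
  hrr <- (142 - 58) / (196 - 58)
  expect_equal(compute_trimp(60, 142, 58, 196),
               60 * hrr * 0.64 * exp(1.92 * hrr), tolerance = 1e-12)
  expect_equal(round(compute_trimp(60, 142, 58, 196), 2), 75.21)
  expect_error(compute_trimp(60, 142, 200, 196), "hr_rest")
  expect_error(compute_trimp(-1, 142, 58, 196), "duration")
  expect_error(compute_trimp(60, 40, 58, 196), "hr_mean")
  # strictly increasing in duration and mean heart rate
  expect_true(all(diff(compute_trimp(1:100, 142, 58, 196)) > 0))
  expect_true(all(diff(compute_trimp(60, seq(60, 196, 2), 58, 196)) > 0))
  # homogeneous of degree 1 in duration
  expect_equal(compute_trimp(90, 150, 58, 196),
               3 * compute_trimp(30, 150, 58, 196))
})

test_that("session-RPE load is the plain product", {
  expect_equal(compute_srpe(0, 75), 0)
  expect_equal(compute_srpe(7, 60), 420)
  expect_equal(compute_srpe(6.3, 60), 378)
  expect_equal(compute_srpe(5, 90), 5 * compute_srpe(5, 18))
  expect_error(compute_srpe(11, 60), "rpe")
  expect_error(compute_srpe(5, -1), "duration")
})

test_that("percent heart-rate reserve is clipped linear scaling", {
  expect_equal(compute_pct_hrr(58, 58, 196), 0)
  expect_equal(compute_pct_hrr(196, 58, 196), 100)
  expect_equal(compute_pct_hrr(142, 58, 196), 100 * 84 / 138, tolerance = 1e-9)
  expect_equal(round(compute_pct_hrr(142, 58, 196), 2), 60.87)
  expect_equal(compute_pct_hrr(40, 58, 196), 0)  # clipped below
  expect_error(compute_pct_hrr(100, 196, 58), "hr_rest")
})

test_that("zone minutes respect the %HRmax boundaries and conserve time", {
  hrmax <- 200
  expect_equal(unname(compute_zone_minutes(rep(0.95 * hrmax, 12), hrmax)),
               c(0, 0, 0, 0, 12))
  expect_equal(unname(compute_zone_minutes(rep(0.40 * hrmax, 8), hrmax)),
               c(0, 0, 0, 0, 0))
  mixed <- c(rep(0.65 * hrmax, 10), rep(0.85 * hrmax, 5))
  expect_equal(unname(compute_zone_minutes(mixed, hrmax)), c(0, 10, 0, 5, 0))
  expect_error(compute_zone_minutes(numeric(0), hrmax), "non-empty")
  # conservation: zoned + unzoned = series length, for random series
  set.seed(1)
  for (i in 1:10) {
    hr <- runif(60, 0.3, 1.05) * hrmax
    z <- compute_zone_minutes(hr, hrmax)
    unzoned <- sum(hr / hrmax * 100 < 50)
    expect_equal(sum(z) + unzoned, 60)
  }
})

test_that("Player Load accumulates inter-sample acceleration change", {
  expect_equal(compute_player_load(rep(1, 50), rep(0, 50), rep(0.5, 50)), 0)
  expect_equal(compute_player_load(c(0, 0.3), c(0, 0.4), c(1, 1)), 0.005)
  expect_error(compute_player_load(1, 1, 1), "2 samples")
  set.seed(2)
  a <- matrix(rnorm(300), ncol = 3)
  b <- matrix(rnorm(150), ncol = 3)
  # additive over concatenation up to the junction step
  junction <- sqrt(sum((b[1, ] - a[100, ])^2)) / 100
  expect_equal(compute_player_load(rbind(a, b)),
               compute_player_load(a) + compute_player_load(b) + junction,
               tolerance = 1e-12)
  # invariant to constant offsets on all axes
  expect_equal(compute_player_load(a + 5), compute_player_load(a),
               tolerance = 1e-9)
})

test_that("heart-rate recovery is the post-exercise decline", {
  r <- compute_hr_recovery(180, 150, 130)
  expect_equal(c(r$hrr_1min, r$hrr_2min), c(30, 50))
  expect_false(r$flagged)
  flat <- compute_hr_recovery(180, 180, 180)
  expect_equal(c(flat$hrr_1min, flat$hrr_2min), c(0, 0))
  expect_warning(neg <- compute_hr_recovery(160, 165, 150), "negative")
  expect_equal(c(neg$hrr_1min, neg$hrr_2min), c(-5, 10))
  expect_true(neg$flagged)
})

test_that("EWMA-ACWR matches hand computation and the stated conventions", {
  const <- compute_ewma_acwr(rep(250, 40))
  expect_true(all(abs(const$acwr - 1) < 1e-12))
  two <- compute_ewma_acwr(c(300, 600))
  expect_equal(two$acute_ewma[2], 0.25 * 600 + 0.75 * 300)
  expect_equal(two$chronic_ewma[2], (2 / 29) * 600 + (27 / 29) * 300,
               tolerance = 1e-9)
  expect_equal(round(two$acute_ewma[2], 2), 375)
  expect_equal(round(two$chronic_ewma[2], 2), 320.69)
  expect_equal(round(two$acwr[2], 3), 1.169)
  zero <- compute_ewma_acwr(rep(0, 10))
  expect_true(all(zero$acwr == 1))
  expect_error(compute_ewma_acwr(c(10, -1)), "non-negative")
})

test_that("EWMA recursion agrees with the unrolled closed form to 1e-12", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    loads <- runif(n, 0, 800) * rbinom(n, 1, 0.7)
    got <- compute_ewma_acwr(loads)
    expect_equal(got$acute_ewma, ewma_unrolled(loads, 7), tolerance = 1e-12)
    expect_equal(got$chronic_ewma, ewma_unrolled(loads, 28), tolerance = 1e-12)
  }
})

test_that("a sustained load step sends ACWR above 1 then monotonically back", {
  loads <- c(rep(200, 40), rep(400, 60))
  acwr <- compute_ewma_acwr(loads)$acwr
  after <- acwr[41:100]
  expect_gt(max(after), 1)
  peak <- which.max(after)
  expect_true(all(diff(after[peak:length(after)]) <= 1e-12))
  expect_lt(abs(after[length(after)] - 1), 0.02)
})

test_that("weekly monotony and strain follow the Foster definitions", {
  wk <- c(200, 300, 400, 300, 200, 300, 400)
  got <- compute_week_monotony_strain(wk)
  expect_equal(got$monotony, 300 / sd(wk), tolerance = 1e-12)
  expect_equal(round(got$monotony, 3), 3.674)
  expect_equal(got$strain, sum(wk) * 300 / sd(wk), tolerance = 1e-12)
  expect_equal(round(got$strain, 1), 7715.9)
  expect_true(is.na(compute_week_monotony_strain(rep(300, 7))$monotony))
  expect_true(is.na(compute_week_monotony_strain(rep(0, 7))$strain))
  expect_error(compute_week_monotony_strain(rep(100, 6)), "7")
})

test_that("rolling baselines use strictly prior days and the min_obs gate", {
  df <- tibble::tibble(day_index = 1:8,
                       value = c(4.0, 4.1, 4.2, 4.0, 4.1, 4.2, 4.0, 9.9))
  rb <- rolling_baseline(df, value, window = 7, min_obs = 3)
  expect_equal(rb$baseline_value[8], mean(df$value[1:7]), tolerance = 1e-12)
  expect_equal(round(rb$baseline_value[8], 4), 4.0857)
  expect_true(all(is.na(rb$baseline_value[1:3])))  # fewer than 3 priors
  expect_equal(rb$n_contributing[4], 3L)
  # constant series returns the constant once enough priors exist
  cc <- rolling_baseline(tibble::tibble(day_index = 1:10, value = 5), value)
  expect_true(all(cc$baseline_value[4:10] == 5))
  # the current day's value never leaks into its own baseline
  spike <- rolling_baseline(df, value)
  expect_lt(spike$baseline_value[8], 5)
})

test_that("derive_loads produces one row per athlete-day with lag-safe windows", {
  dat <- cached_sim(1)
  der <- derive_loads(dat$sessions, dat$athletes, dat$calendar)
  expect_equal(nrow(der), nrow(dat$athletes) * nrow(dat$calendar))
  expect_true(all(der$acwr >= 0))
  # trailing weekly aggregates undefined in the first week
  expect_true(all(is.na(der$week_monotony[der$day_index <= 6])))
  one <- der[der$athlete_id == der$athlete_id[1], ]
  ew <- compute_ewma_acwr(one$daily_load)
  expect_equal(one$acwr, ew$acwr, tolerance = 1e-12)
  # strain = weekly total x monotony wherever defined
  def <- !is.na(der$week_monotony)
  wk_tot <- der$week_strain[def] / der$week_monotony[def]
  expect_true(all(wk_tot >= 0 | is.na(wk_tot)))
})
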