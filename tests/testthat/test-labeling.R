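test_that("the joint 2-of-4 rule reproduces worked examples", {
  # wellness 13 + two consecutive RPE >= 8, other criteria clean -> fatigued
  a <- evaluate_fatigue_criteria(criterion_row(wellness_total = 13,
                                               rpe_today = 8, rpe_prev = 9,
                                               cmj_drop = 0.05,
                                               hrv_drop = 0.2))
  expect_equal(a$n_met, 2L)
  expect_equal(as.character(a$label), "fatigued")

  # a single met criterion is not fatigue
  b <- evaluate_fatigue_criteria(criterion_row(wellness_total = 14))
  expect_equal(b$n_met, 1L)
  expect_equal(as.character(b$label), "non_fatigued")

  # CMJ drop 12% plus LnRMSSD drop 0.6 -> fatigued
  cc <- evaluate_fatigue_criteria(criterion_row(cmj_drop = 0.12,
                                                hrv_drop = 0.6))
  expect_equal(cc$n_met, 2L)
  expect_equal(as.character(cc$label), "fatigued")
})

test_that("criterion thresholds are sharp at the printed boundaries", {
  # wellness exactly 15 is NOT met (< 15)
  expect_equal(as.character(
    evaluate_fatigue_criteria(criterion_row(wellness_total = 15))$wellness_flag
  ), "not_met")
  expect_equal(as.character(
    evaluate_fatigue_criteria(criterion_row(wellness_total = 14.99))$wellness_flag
  ), "met")
  # CMJ drop exactly 10% is NOT met (> 10%)
  expect_equal(as.character(
    evaluate_fatigue_criteria(criterion_row(cmj_drop = 0.10))$cmj_flag
  ), "not_met")
  expect_equal(as.character(
    evaluate_fatigue_criteria(criterion_row(cmj_drop = 0.1001))$cmj_flag
  ), "met")
  # LnRMSSD drop exactly 0.5 is NOT met (> 0.5)
  expect_equal(as.character(
    evaluate_fatigue_criteria(criterion_row(hrv_drop = 0.5))$hrv_flag
  ), "not_met")
  # RPE exactly 8 on both days IS met (>= 8)
  expect_equal(as.character(
    evaluate_fatigue_criteria(criterion_row(rpe_today = 8,
                                            rpe_prev = 8))$rpe_flag
  ), "met")
  # a rest day yesterday breaks the run
  expect_equal(as.character(
    evaluate_fatigue_criteria(criterion_row(rpe_today = 9,
                                            rpe_prev = NA))$rpe_flag
  ), "not_met")
  # no session today -> not evaluable
  expect_equal(as.character(
    evaluate_fatigue_criteria(criterion_row(rpe_today = NA))$rpe_flag
  ), "not_evaluable")
})

test_that("missing inputs degrade to not_evaluable and gate labelling", {
  sparse <- evaluate_fatigue_criteria(criterion_row(
    cmj_drop = NA, hrv_drop = NA, wellness_total = 13, rpe_today = NA
  ))
  expect_equal(sparse$n_evaluable, 1L)
  expect_equal(as.character(sparse$label), "unlabelable")
  expect_true(sparse$n_met <= sparse$n_evaluable)
})

test_that("switching a criterion on never flips fatigued to non_fatigued", {
  set.seed(5)
  for (i in 1:200) {
    row <- criterion_row(
      cmj_drop = sample(c(NA, runif(1, -0.1, 0.25)), 1),
      hrv_drop = sample(c(NA, runif(1, -0.5, 1.0)), 1),
      wellness_total = sample(c(NA, sample(5:25, 1)), 1),
      rpe_today = sample(c(NA, sample(0:10, 1)), 1),
      rpe_prev = sample(c(NA, sample(0:10, 1)), 1)
    )
    before <- evaluate_fatigue_criteria(row)
    # force one currently unmet criterion to met
    improved <- row
    improved$wellness_total <- 5
    after <- evaluate_fatigue_criteria(improved)
    if (as.character(before$label) == "fatigued") {
      expect_equal(as.character(after$label), "fatigued")
    }
    expect_gte(after$n_met, before$n_met -
                 (as.character(before$wellness_flag) == "met"))
  }
})

test_that("labelling is pure and independent of row order", {
  set.seed(6)
  rows <- dplyr::bind_rows(lapply(1:50, function(i) {
    criterion_row(day_index = i,
                  cmj_drop = runif(1, -0.1, 0.2),
                  hrv_drop = runif(1, -0.5, 1),
                  wellness_total = sample(5:25, 1),
                  rpe_today = sample(0:10, 1), rpe_prev = sample(0:10, 1))
  }))
  straight <- evaluate_fatigue_criteria(rows)
  shuffled <- evaluate_fatigue_criteria(rows[sample(nrow(rows)), ]) %>%
    dplyr::arrange(day_index)
  expect_equal(as.character(straight$label), as.character(shuffled$label))
  expect_identical(evaluate_fatigue_criteria(rows), straight)
})

test_that("an engineered 10-day table labels exactly its 4 fatigue days", {
  # days 3,5,8,9 engineered to meet two criteria each; the rest clean
  fix <- dplyr::bind_rows(lapply(1:10, function(d) {
    if (d %in% c(3, 5)) {
      criterion_row(day_index = d, wellness_total = 12, hrv_drop = 0.8)
    } else if (d %in% c(8, 9)) {
      criterion_row(day_index = d, cmj_drop = 0.15, rpe_today = 9,
                    rpe_prev = 8)
    } else {
      criterion_row(day_index = d)
    }
  }))
  out <- evaluate_fatigue_criteria(fix)
  expect_equal(sum(out$label == "fatigued"), 4)
  expect_equal(out$day_index[out$label == "fatigued"], c(3, 5, 8, 9))
})

test_that("an all-healthy cohort yields zero prevalence", {
  cal <- generate_calendar(2, 2)
  athletes <- mean_profile(3)
  days <- cal$day_index
  morning <- tidyr::expand_grid(athlete_id = athletes$athlete_id,
                                day_index = days) %>%
    dplyr::mutate(lnrmssd = 4.2, wellness_total = 20, resting_hr = 58,
                  rmssd = exp(4.2))
  sessions <- tidyr::expand_grid(athlete_id = athletes$athlete_id,
                                 day_index = days[cal$day_type != "rest"]) %>%
    dplyr::mutate(rpe = 4L, duration = 90, total_distance = 5000,
                  hsr_distance = 300, sprint_distance = 80,
                  player_load = 450, hr_mean = 140)
  tests <- tidyr::expand_grid(athlete_id = athletes$athlete_id,
                              day_index = days[cal$is_test_day]) %>%
    dplyr::mutate(cmj_height = 38.6, cmj_peak_power = 3200, sprint10 = 1.78)
  lab <- label_fatigue(list(sessions = sessions, morning = morning,
                            tests = tests, calendar = cal))
  expect_equal(lab$summary$n_fatigued, 0)
  expect_equal(lab$summary$prevalence_pct, 0)
})

test_that("cohort labelling hits the configured prevalence band", {
  lab <- cached_labels(1)
  expect_gt(lab$summary$prevalence_pct, 15.2 - 3)
  expect_lt(lab$summary$prevalence_pct, 15.2 + 3)
  # elevated incidence on days 1-2 after a match
  expect_gt(lab$summary$post_match_incidence_pct,
            lab$summary$other_incidence_pct)
  # conservation: labelled = fatigued + non-fatigued
  tab <- table(lab$labels$label)
  expect_equal(unname(tab["fatigued"] + tab["non_fatigued"]),
               lab$summary$n_labeled)
})

test_that("tightening thresholds cannot increase prevalence", {
  dat <- cached_sim(1)
  prev <- vapply(c(15, 13, 11), function(w) {
    label_fatigue(dat, fatigue_criteria(wellness_threshold = w)
    )$summary$prevalence_pct
  }, numeric(1))
  expect_true(all(diff(prev) <= 0))
})
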