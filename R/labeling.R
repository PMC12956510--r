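tri_state <- function(met, evaluable) {
  factor(ifelse(!evaluable, "not_evaluable", ifelse(met, "met", "not_met")),
         levels = c("met", "not_met", "not_evaluable"))
}

#' Evaluate the four fatigue criteria for athlete-days
#'
#' Applies the operational fatigue rule to pre-assembled per-day inputs.
#' The four criteria are (1) CMJ height drop greater than 10% of the rolling
#' individual test baseline, (2) morning LnRMSSD more than 0.5 below the
#' 7-day rolling baseline, (3) wellness total below 15 of 25, and (4) session
#' RPE at or above 8 on two consecutive session days. A criterion whose
#' inputs are unavailable is `not_evaluable`; a day is labelled `fatigued`
#' when at least `min_criteria` evaluable criteria are met, `non_fatigued`
#' otherwise, and `unlabelable` when fewer than `min_evaluable` criteria
#' could be evaluated.
#'
#' @param daily tibble with columns `athlete_id`, `day_index`, `cmj_drop`
#'   (fractional drop vs baseline; `NA` = not evaluable), `hrv_drop`
#'   (baseline LnRMSSD minus today's; `NA` = not evaluable),
#'   `wellness_total` (`NA` = not evaluable), `rpe_today` and `rpe_prev`
#'   (maximum session RPE on the day and the previous calendar day; `NA`
#'   means no session/missing — today `NA` makes the criterion not
#'   evaluable, yesterday `NA` breaks the consecutive run).
#' @param criteria a [fatigue_criteria()] configuration.
#' @return The input keyed columns plus tri-state flags (`cmj_flag`,
#'   `hrv_flag`, `wellness_flag`, `rpe_flag`), `n_met`, `n_evaluable` and
#'   `label`.
#' @export
evaluate_fatigue_criteria <- function(daily, criteria = fatigue_criteria()) {
  if (criteria$rpe_consecutive_days != 2L)
    abort("only rpe_consecutive_days = 2 is supported.")
  cmj_ok <- !is.na(daily$cmj_drop)
  hrv_ok <- !is.na(daily$hrv_drop)
  wel_ok <- !is.na(daily$wellness_total)
  rpe_ok <- !is.na(daily$rpe_today)

  cmj_met <- cmj_ok & daily$cmj_drop > criteria$cmj_drop_threshold
  hrv_met <- hrv_ok & daily$hrv_drop > criteria$lnrmssd_drop_threshold
  wel_met <- wel_ok & daily$wellness_total < criteria$wellness_threshold
  rpe_met <- rpe_ok & daily$rpe_today >= criteria$rpe_threshold &
    !is.na(daily$rpe_prev) & daily$rpe_prev >= criteria$rpe_threshold

  n_met <- cmj_met + hrv_met + wel_met + rpe_met
  n_evaluable <- cmj_ok + hrv_ok + wel_ok + rpe_ok
  label <- ifelse(n_evaluable < criteria$min_evaluable, "unlabelable",
                  ifelse(n_met >= criteria$min_criteria, "fatigued",
                         "non_fatigued"))
  daily %>%
    mutate(
      cmj_flag = tri_state(cmj_met, cmj_ok),
      hrv_flag = tri_state(hrv_met, hrv_ok),
      wellness_flag = tri_state(wel_met, wel_ok),
      rpe_flag = tri_state(rpe_met, rpe_ok),
      n_met = as.integer(n_met),
      n_evaluable = as.integer(n_evaluable),
      label = factor(label,
                     levels = c("fatigued", "non_fatigued", "unlabelable"))
    )
}

# CMJ criterion state per athlete-day: drop vs the mean of up to
# `n_base` prior tests, evaluated on the test day and carried <= carry days
cmj_drop_by_day <- function(tests, day_range, criteria) {
  out <- tibble(athlete_id = character(), day_index = integer(),
                cmj_drop = numeric())
  if (is.null(tests) || nrow(tests) == 0) return(out)
  tests %>%
    filter(!is.na(cmj_height)) %>%
    arrange(athlete_id, day_index) %>%
    group_by(athlete_id) %>%
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 2) return(tibble(day_index = integer(), cmj_drop = numeric()))
      rows <- lapply(2:n, function(i) {
        prior <- df$cmj_height[max(1, i - criteria$cmj_baseline_tests):(i - 1)]
        drop <- (mean(prior) - df$cmj_height[i]) / mean(prior)
        days <- df$day_index[i] + 0:criteria$cmj_carry_days
        # carry only until the next test
        if (i < n) days <- days[days < df$day_index[i + 1]]
        tibble(day_index = as.integer(days), cmj_drop = drop)
      })
      bind_rows(rows)
    }) %>%
    ungroup() %>%
    filter(day_index %in% day_range)
}

#' Label a monitoring cohort for fatigue
#'
#' Builds the four criterion inputs from the monitoring tables (rolling
#' LnRMSSD baseline, carried-forward CMJ drop, wellness total, consecutive
#' high-RPE session days), applies [evaluate_fatigue_criteria()] to every
#' athlete-day of the calendar, and summarises prevalence overall and on
#' days 1-2 after a match versus all other labelled days.
#'
#' @param data named list with `sessions`, `morning`, `tests`, `calendar`
#'   tibbles (as from [simulate_monitoring_data()] or imported CSVs).
#' @param criteria a [fatigue_criteria()].
#' @return A list with `labels` (per athlete-day criterion flags and label)
#'   and `summary` (n labelled, n fatigued, prevalence in percent, and
#'   post-match vs other incidence in percent).
#' @export
#' @examples
#' \donttest{
#' dat <- simulate_monitoring_data(seed = 1)
#' lab <- label_fatigue(dat)
#' lab$summary$prevalence_pct
#' }
label_fatigue <- function(data, criteria = fatigue_criteria()) {
  if (nrow(data$morning) == 0) abort("empty morning table.")
  calendar <- data$calendar
  day_range <- calendar$day_index

  base <- rolling_baseline(
    select(data$morning, athlete_id, day_index, lnrmssd),
    lnrmssd, window = criteria$hrv_window, min_obs = criteria$hrv_min_obs
  ) %>% select(athlete_id, day_index, baseline_value)

  morning <- data$morning %>%
    select(athlete_id, day_index, lnrmssd, wellness_total) %>%
    left_join(base, by = c("athlete_id", "day_index")) %>%
    mutate(hrv_drop = baseline_value - lnrmssd)

  rpe_daily <- data$sessions %>%
    filter(!is.na(rpe)) %>%
    group_by(athlete_id, day_index) %>%
    summarise(rpe_today = max(rpe), .groups = "drop")

  athletes <- unique(c(data$morning$athlete_id, data$sessions$athlete_id))
  grid <- tidyr::expand_grid(athlete_id = athletes, day_index = day_range) %>%
    left_join(morning, by = c("athlete_id", "day_index")) %>%
    left_join(rpe_daily, by = c("athlete_id", "day_index")) %>%
    arrange(athlete_id, day_index) %>%
    group_by(athlete_id) %>%
    mutate(rpe_prev = lag(rpe_today)) %>%
    ungroup() %>%
    left_join(cmj_drop_by_day(data$tests, day_range, criteria),
              by = c("athlete_id", "day_index"))

  labels <- evaluate_fatigue_criteria(
    select(grid, athlete_id, day_index, cmj_drop, hrv_drop, wellness_total,
           rpe_today, rpe_prev),
    criteria
  )

  match_days <- calendar$day_index[calendar$day_type == "match"]
  labels <- labels %>%
    mutate(days_since_match = days_since_event(day_index, match_days))

  labelled <- filter(labels, label != "unlabelable")
  post <- filter(labelled, days_since_match %in% c(1, 2))
  other <- filter(labelled, !days_since_match %in% c(1, 2))
  pct <- function(x) if (nrow(x) == 0) NA_real_ else
    100 * mean(x$label == "fatigued")

  list(
    labels = labels,
    summary = list(
      n_days = nrow(labels),
      n_labeled = nrow(labelled),
      n_fatigued = sum(labelled$label == "fatigued"),
      prevalence_pct = pct(labelled),
      post_match_incidence_pct = pct(post),
      other_incidence_pct = pct(other)
    )
  )
}

# days since the most recent strictly prior event day (NA before the first)
days_since_event <- function(day_index, event_days) {
  if (length(event_days) == 0) return(rep(NA_real_, length(day_index)))
  ev <- sort(event_days)
  vapply(day_index, function(d) {
    prior <- ev[ev < d]
    if (length(prior) == 0) NA_real_ else d - max(prior)
  }, numeric(1))
}
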