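#' Banister training impulse (TRIMP)
#'
#' `TRIMP = duration * HRr * a * exp(b * HRr)` with
#' `HRr = (hr_mean - hr_rest) / (hr_max - hr_rest)` the fractional heart-rate
#' reserve. The default weighting constants are the male-form Banister
#' coefficients `a = 0.64`, `b = 1.92`.
#'
#' @param duration session duration in minutes (>= 0).
#' @param hr_mean mean session heart rate (bpm), between `hr_rest` and
#'   `hr_max`.
#' @param hr_rest,hr_max individual resting and maximal heart rate (bpm).
#' @param weight_a,weight_b positive Banister weighting constants.
#' @return TRIMP in arbitrary units. Vectorised over all arguments.
#' @export
#' @examples
#' compute_trimp(60, 142, 58, 196)
compute_trimp <- function(duration, hr_mean, hr_rest, hr_max,
                          weight_a = 0.64, weight_b = 1.92) {
  stopifnot(weight_a > 0, weight_b > 0)
  if (any(hr_rest >= hr_max, na.rm = TRUE))
    abort("hr_rest must be below hr_max.")
  if (any(duration < 0, na.rm = TRUE)) abort("duration must be non-negative.")
  if (any(hr_mean < hr_rest | hr_mean > hr_max, na.rm = TRUE))
    abort("hr_mean must lie between hr_rest and hr_max.")
  hrr <- (hr_mean - hr_rest) / (hr_max - hr_rest)
  duration * hrr * weight_a * exp(weight_b * hrr)
}

#' Session-RPE load
#'
#' `sRPE = RPE * duration` in arbitrary units (Borg CR-10 score times
#' session minutes).
#'
#' @param rpe perceived exertion on the 0-10 scale.
#' @param duration session duration in minutes (>= 0).
#' @return sRPE in AU, vectorised.
#' @export
compute_srpe <- function(rpe, duration) {
  if (any(rpe < 0 | rpe > 10, na.rm = TRUE)) abort("rpe must lie in [0, 10].")
  if (any(duration < 0, na.rm = TRUE)) abort("duration must be non-negative.")
  rpe * duration
}

#' Percentage of heart-rate reserve
#'
#' `100 * (hr - hr_rest) / (hr_max - hr_rest)`, clipped to `[0, 100]`.
#'
#' @param hr heart rate (bpm).
#' @param hr_rest,hr_max resting and maximal heart rate (bpm), with
#'   `hr_rest < hr_max`.
#' @return Percent of reserve, vectorised.
#' @export
compute_pct_hrr <- function(hr, hr_rest, hr_max) {
  if (any(hr_rest >= hr_max, na.rm = TRUE))
    abort("hr_rest must be below hr_max.")
  pmin(100, pmax(0, 100 * (hr - hr_rest) / (hr_max - hr_rest)))
}

#' Heart-rate intensity-zone minutes
#'
#' Assigns each per-minute heart-rate sample to one of five zones defined on
#' percent of maximal heart rate (50-60, 60-70, 70-80, 80-90, 90-100+ %HRmax;
#' minutes below 50% are unzoned). Each minute lands in at most one zone, so
#' zone minutes plus unzoned minutes equal the series length.
#'
#' @param hr_series numeric vector of per-minute heart rates (bpm).
#' @param hr_max individual maximal heart rate (bpm).
#' @return Named numeric vector of minutes in zones 1-5.
#' @export
#' @examples
#' compute_zone_minutes(c(rep(0.65, 10), rep(0.85, 5)) * 200, 200)
compute_zone_minutes <- function(hr_series, hr_max) {
  if (length(hr_series) == 0) abort("hr_series must be non-empty.")
  pct <- hr_series / hr_max * 100
  zone <- findInterval(pct, c(50, 60, 70, 80, 90))  # 0 = below floor
  counts <- tabulate(zone, nbins = 5)
  setNames(as.numeric(counts), paste0("zone", 1:5))
}

#' Accelerometer Player Load
#'
#' Accumulated instantaneous rate of change of tri-axial acceleration:
#' `PL = sum_t sqrt(d_ax^2 + d_ay^2 + d_az^2) / 100` over successive samples.
#' Invariant to a constant offset on any axis and additive over concatenated
#' traces (up to the junction step).
#'
#' @param ax,ay,az numeric acceleration series in g (equal length, >= 2
#'   samples), or `ax` may be a 3-column matrix/data frame.
#' @return Player Load in AU.
#' @export
#' @examples
#' compute_player_load(c(0, 0.3), c(0, 0.4), c(1, 1))
compute_player_load <- function(ax, ay = NULL, az = NULL) {
  if (is.data.frame(ax)) {
    stopifnot(ncol(ax) == 3)
    az <- ax[[3]]; ay <- ax[[2]]; ax <- ax[[1]]
  } else if (is.matrix(ax)) {
    stopifnot(ncol(ax) == 3)
    az <- ax[, 3]; ay <- ax[, 2]; ax <- ax[, 1]
  }
  if (length(ax) < 2) abort("trace must have at least 2 samples.")
  stopifnot(length(ax) == length(ay), length(ay) == length(az))
  sum(sqrt(diff(ax)^2 + diff(ay)^2 + diff(az)^2)) / 100
}

#' Post-exercise heart-rate recovery
#'
#' Heart-rate decline at one and two minutes after exercise end. Negative
#' recoveries (heart rate rising after the session) are returned as-is with
#' a warning flag.
#'
#' @param end_hr heart rate at exercise end (bpm).
#' @param hr_60s,hr_120s heart rate 60 s and 120 s later (bpm).
#' @return A tibble with `hrr_1min`, `hrr_2min` (beats) and `flagged`
#'   (`TRUE` when either recovery is negative).
#' @export
compute_hr_recovery <- function(end_hr, hr_60s, hr_120s) {
  stopifnot(all(end_hr > 0), all(hr_60s > 0), all(hr_120s > 0))
  h1 <- end_hr - hr_60s
  h2 <- end_hr - hr_120s
  flagged <- h1 < 0 | h2 < 0
  if (any(flagged)) warn("negative heart-rate recovery flagged.")
  tibble(hrr_1min = h1, hrr_2min = h2, flagged = flagged)
}

#' EWMA acute:chronic workload ratio
#'
#' Exponentially weighted moving averages of the daily load with spans of
#' `acute_span` and `chronic_span` days (`lambda = 2 / (span + 1)`), both
#' initialised at the first day's load, with the uncoupled ratio
#' `ACWR = acute / chronic`. When both averages are zero the ratio is
#' defined as 1.
#'
#' @param daily_loads chronologically ordered non-negative daily loads (AU);
#'   rest days enter as 0.
#' @param acute_span,chronic_span spans in days, `chronic_span > acute_span >= 1`.
#' @return A tibble with `daily_load`, `acute_ewma`, `chronic_ewma`, `acwr`.
#' @export
#' @examples
#' compute_ewma_acwr(c(300, 600))
compute_ewma_acwr <- function(daily_loads, acute_span = 7, chronic_span = 28) {
  stopifnot(chronic_span > acute_span, acute_span >= 1)
  if (any(daily_loads < 0, na.rm = TRUE)) abort("loads must be non-negative.")
  loads <- daily_loads
  loads[is.na(loads)] <- 0
  n <- length(loads)
  la <- 2 / (acute_span + 1)
  lc <- 2 / (chronic_span + 1)
  ewma <- function(lambda) {
    out <- numeric(n)
    out[1] <- loads[1]
    for (t in seq_len(n)[-1]) out[t] <- lambda * loads[t] + (1 - lambda) * out[t - 1]
    out
  }
  acute <- ewma(la)
  chronic <- ewma(lc)
  acwr <- ifelse(acute == 0 & chronic == 0, 1, acute / chronic)
  tibble(daily_load = daily_loads, acute_ewma = acute,
         chronic_ewma = chronic, acwr = acwr)
}

#' Weekly training monotony and strain
#'
#' `monotony = mean(daily load) / sd(daily load)` over one seven-day week
#' (rest days as zeros; sample SD with n-1), and
#' `strain = weekly total load * monotony`. A week with zero load SD has
#' undefined monotony and strain, returned as `NA` (flagged missing rather
#' than capped).
#'
#' @param daily_loads numeric vector of exactly 7 daily loads (AU).
#' @return A tibble with `monotony` and `strain`.
#' @export
#' @examples
#' compute_week_monotony_strain(c(200, 300, 400, 300, 200, 300, 400))
compute_week_monotony_strain <- function(daily_loads) {
  if (length(daily_loads) != 7) abort("daily_loads must have exactly 7 values.")
  s <- sd(daily_loads)
  if (is.na(s) || s == 0) return(tibble(monotony = NA_real_, strain = NA_real_))
  monotony <- mean(daily_loads) / s
  tibble(monotony = monotony, strain = sum(daily_loads) * monotony)
}

#' Rolling individual baseline
#'
#' Mean of the available values over the strictly prior `window` days
#' (`[t - window, t - 1]`), emitted only when at least `min_obs` values
#' contribute. Groups by `athlete_id` when present.
#'
#' @param data tibble with `day_index`, the value column, and optionally
#'   `athlete_id`.
#' @param var name of the value column (string or bare name).
#' @param window lookback in days (default 7).
#' @param min_obs minimum contributing observations (default 3).
#' @return A tibble `athlete_id` (if present), `day_index`, `variable`,
#'   `baseline_value` (`NA` when under-observed), `n_contributing`.
#' @export
rolling_baseline <- function(data, var, window = 7, min_obs = 3) {
  stopifnot(window >= 1)
  var <- rlang::as_name(rlang::ensym(var))
  roll_one <- function(df) {
    df <- arrange(df, day_index)
    d <- df$day_index
    v <- df[[var]]
    base <- vapply(seq_along(d), function(i) {
      sel <- d >= d[i] - window & d < d[i] & !is.na(v)
      if (sum(sel) >= min_obs) mean(v[sel]) else NA_real_
    }, numeric(1))
    nc <- vapply(seq_along(d), function(i) {
      sum(d >= d[i] - window & d < d[i] & !is.na(v))
    }, numeric(1))
    tibble(day_index = d, variable = var, baseline_value = base,
           n_contributing = as.integer(nc))
  }
  if ("athlete_id" %in% names(data)) {
    data %>%
      group_by(athlete_id) %>%
      dplyr::group_modify(~ roll_one(.x)) %>%
      ungroup()
  } else {
    roll_one(data)
  }
}

#' Athlete-day derived load table
#'
#' Aggregates sessions to athlete-days over the full calendar (rest days as
#' zero load), computes TRIMP, sRPE and mean %HRR per day, the EWMA
#' acute:chronic workload ratio on the configured load stream, and trailing
#' 7-day monotony/strain (computed over days `t-7 ... t-1` so the value is
#' available before that day's training).
#'
#' @param sessions session tibble (as generated or imported).
#' @param athletes athlete tibble carrying `hr_rest`, `hr_max`.
#' @param calendar calendar tibble defining the day range.
#' @param load_metric which stream feeds ACWR/monotony/strain: `"srpe"`
#'   (default) or `"trimp"`.
#' @param acute_span,chronic_span EWMA spans in days.
#' @return A tibble with one row per athlete per calendar day.
#' @export
derive_loads <- function(sessions, athletes, calendar,
                         load_metric = c("srpe", "trimp"),
                         acute_span = 7, chronic_span = 28) {
  load_metric <- match.arg(load_metric)
  ses <- sessions %>%
    left_join(select(athletes, athlete_id, hr_rest, hr_max), by = "athlete_id") %>%
    mutate(
      trimp = compute_trimp(duration, pmin(pmax(hr_mean, hr_rest), hr_max),
                            hr_rest, hr_max),
      srpe = compute_srpe(rpe, duration),
      pct_hrr = compute_pct_hrr(hr_mean, hr_rest, hr_max)
    )
  daily <- ses %>%
    group_by(athlete_id, day_index) %>%
    summarise(
      total_distance = sum(total_distance, na.rm = TRUE),
      hsr_distance = sum(hsr_distance, na.rm = TRUE),
      player_load = sum(player_load, na.rm = TRUE),
      trimp = sum(trimp, na.rm = TRUE),
      srpe = sum(srpe, na.rm = TRUE),
      pct_hrr = mean(pct_hrr, na.rm = TRUE),
      max_rpe = suppressWarnings(max(rpe, na.rm = TRUE)),
      dplyr::across(dplyr::starts_with("zone"), ~ sum(.x, na.rm = TRUE)),
      .groups = "drop"
    ) %>%
    mutate(max_rpe = ifelse(is.finite(max_rpe), max_rpe, NA_real_))

  grid <- tidyr::expand_grid(athlete_id = athletes$athlete_id,
                             day_index = calendar$day_index) %>%
    left_join(daily, by = c("athlete_id", "day_index")) %>%
    mutate(across(c(total_distance, hsr_distance, player_load, trimp, srpe),
                  ~ tidyr::replace_na(.x, 0))) %>%
    mutate(daily_load = if (load_metric == "srpe") srpe else trimp) %>%
    arrange(athlete_id, day_index)

  grid %>%
    group_by(athlete_id) %>%
    dplyr::group_modify(function(df, key) {
      ew <- compute_ewma_acwr(df$daily_load, acute_span, chronic_span)
      df$acute_ewma <- ew$acute_ewma
      df$chronic_ewma <- ew$chronic_ewma
      df$acwr <- ew$acwr
      # trailing-week aggregates over strictly prior 7 days
      loads <- df$daily_load
      td <- df$total_distance
      n <- length(loads)
      mono <- strain <- wk_td <- rep(NA_real_, n)
      for (t in seq_len(n)) {
        if (t > 7) {
          win <- loads[(t - 7):(t - 1)]
          wk_td[t] <- sum(td[(t - 7):(t - 1)])
          ms <- compute_week_monotony_strain(win)
          mono[t] <- ms$monotony
          strain[t] <- ms$strain
        }
      }
      df$week_monotony <- mono
      df$week_strain <- strain
      df$weekly_total_distance <- wk_td
      df
    }) %>%
    ungroup()
}
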