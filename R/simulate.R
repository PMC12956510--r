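#' Latent fitness-fatigue state
#'
#' A minimal first-order impulse-response state used by the simulator: daily
#' load adds to a non-negative fatigue level that decays exponentially with
#' time constant `decay_tau` (days). The state gives the generated markers
#' and labels a coherent joint structure; it is simulator plumbing, not a
#' measured quantity.
#'
#' @param fatigue_level non-negative latent fatigue (arbitrary units).
#' @param decay_tau decay time constant in days.
#' @param gain_kappa dimensionless gain applied per 100 AU of daily load.
#' @return A list of class `latent_state`.
#' @export
#' @examples
#' s <- latent_state()
#' step_latent_state(s, daily_load = 300)
latent_state <- function(fatigue_level = 0, decay_tau = 5, gain_kappa = 0.8) {
  stopifnot(fatigue_level >= 0, decay_tau > 0, gain_kappa >= 0)
  structure(list(fatigue_level = fatigue_level, decay_tau = decay_tau,
                 gain_kappa = gain_kappa), class = "latent_state")
}

#' Advance the latent fatigue state by one day
#'
#' `F_t = F_{t-1} * exp(-1 / tau) + kappa * load / 100`
#'
#' @param state a [latent_state()].
#' @param daily_load non-negative daily load in AU (TRIMP by default in the
#'   cohort simulator).
#' @return The updated `latent_state`.
#' @export
step_latent_state <- function(state, daily_load) {
  stopifnot(inherits(state, "latent_state"))
  if (any(daily_load < 0)) abort("daily_load must be non-negative.")
  state$fatigue_level <- state$fatigue_level * exp(-1 / state$decay_tau) +
    state$gain_kappa * daily_load / 100
  state
}

# inverse-CDF truncated normal: uses exactly n uniforms, so vectorised draws
# stay reproducible regardless of rejection behaviour
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Generate a synthetic athlete cohort
#'
#' Draws per-athlete constants (position, maximal and resting heart rate,
#' countermovement-jump, LnRMSSD and 10 m sprint baselines, attendance rate)
#' from the configured marginal distributions. Positions follow the supplied
#' head-count mix.
#'
#' @param n_athletes number of athletes (at least 4).
#' @param position_mix named integer vector (`GK`, `DF`, `MF`, `FW`) summing
#'   to `n_athletes`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @param config cohort block of [sim_config()].
#' @return A tibble with one row per athlete.
#' @export
#' @examples
#' generate_cohort(seed = 1)
generate_cohort <- function(n_athletes = 48L,
                            position_mix = c(GK = 3L, DF = 15L, MF = 18L, FW = 12L),
                            seed = NULL,
                            config = sim_config()$cohort) {
  if (n_athletes < 4) abort("n_athletes must be at least 4.")
  if (sum(position_mix) != n_athletes)
    abort("position_mix must sum to n_athletes.")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_athletes)
  pos <- factor(rep(names(position_mix), times = position_mix),
                levels = c("GK", "DF", "MF", "FW"))
  hr_max <- rtruncnorm(n, config$hr_max["mean"], config$hr_max["sd"], 170, 225)
  hr_rest <- rtruncnorm(n, config$hr_rest["mean"], config$hr_rest["sd"], 40, 78)
  hr_rest <- pmin(hr_rest, hr_max - 80)  # keep a physiological reserve
  tibble(
    athlete_id = sprintf("ath%02d", seq_len(n)),
    position = pos,
    hr_max = round(hr_max, 1),
    hr_rest = round(hr_rest, 1),
    cmj_baseline = round(rtruncnorm(n, config$cmj_baseline["mean"],
                                    config$cmj_baseline["sd"], 24, 56), 1),
    lnrmssd_baseline = round(rtruncnorm(n, config$lnrmssd_baseline["mean"],
                                        config$lnrmssd_baseline["sd"], 3.3, 5.1), 3),
    sprint10_baseline = round(rtruncnorm(n, config$sprint10_baseline["mean"],
                                         config$sprint10_baseline["sd"], 1.5, 2.1), 3),
    attendance_rate = pmin(1, pmax(0.7, rnorm(n, config$attendance_rate["mean"],
                                              config$attendance_rate["sd"]))),
    wellness_base = pmin(4.8, pmax(2.8, rnorm(n, config$wellness_item_base["mean"] %||% 3.95,
                                              config$wellness_item_base["sd"] %||% 0.28)))
  )
}

#' Generate the training/match calendar
#'
#' Lays out `weeks` seven-day weeks starting on a Monday. Mondays are
#' recovery days carrying the weekly neuromuscular tests; Sundays are rest.
#' The remaining five days are scheduled team days; match days replace
#' training on a fixed priority of weekdays (Saturday, Wednesday, Friday,
#' Tuesday, Thursday, then Sunday), filled week by week so match density is
#' even. Phases follow the periodisation: weeks 1-4 progressive loading,
#' weeks 5-10 maintenance, weeks 11-12 taper (weeks beyond 10 always taper
#' in shorter calendars only if configured).
#'
#' @param weeks number of weeks (>= 1).
#' @param matches number of match days; at most `6 * weeks`.
#' @param seed unused (the layout is deterministic); kept for interface
#'   stability.
#' @return A tibble with `day_index` (0-based), `week_index`, `phase`,
#'   `day_type` and `is_test_day`.
#' @export
#' @examples
#' table(generate_calendar(12, 24)$day_type)
generate_calendar <- function(weeks = 12L, matches = 24L, seed = NULL) {
  if (weeks < 1) abort("weeks must be >= 1.")
  if (matches > 6 * weeks)
    abort("matches exceed the available non-recovery days (6 per week).")
  n_days <- 7L * as.integer(weeks)
  day_index <- 0:(n_days - 1L)
  dow <- day_index %% 7L  # 0 = Monday ... 6 = Sunday
  week_index <- day_index %/% 7L + 1L
  phase <- dplyr::case_when(
    week_index <= 4L ~ "progressive",
    week_index >= 11L ~ "taper",
    TRUE ~ "maintenance"
  )
  if (weeks < 11) phase[week_index > 4L] <- "maintenance"
  day_type <- ifelse(dow %in% c(0L, 6L), "rest", "training")
  match_priority <- c(5L, 2L, 4L, 1L, 3L, 6L)  # Sat, Wed, Fri, Tue, Thu, Sun
  slots <- unlist(lapply(match_priority, function(d) which(dow == d)))
  md <- slots[seq_len(matches)]
  day_type[md] <- "match"
  tibble(
    day_index = day_index,
    week_index = week_index,
    phase = factor(phase, levels = c("progressive", "maintenance", "taper")),
    day_type = factor(day_type, levels = c("training", "match", "rest")),
    is_test_day = dow == 0L
  )
}

# per-day volume scaling implied by the periodisation, normalised to mean 1
# over scheduled session days so cohort marginals are preserved
phase_load_scale <- function(calendar) {
  wk <- calendar$week_index
  raw <- dplyr::case_when(
    calendar$phase == "progressive" ~ 0.86 + 0.16 * (pmin(wk, 4) - 1) / 3,
    calendar$phase == "taper" ~ 0.90,
    TRUE ~ 1.02
  )
  sess <- calendar$day_type != "rest"
  if (any(sess)) raw <- raw / mean(raw[sess])
  raw
}

# position multipliers for one channel, normalised so the mix-weighted mean
# is 1 (cohort marginals stay on target while group contrasts persist)
normalise_multipliers <- function(mult, positions) {
  w <- table(positions)[names(mult)]
  w[is.na(w)] <- 0
  m <- sum(mult * as.numeric(w)) / sum(w)
  mult / m
}

#' Simulate one or more monitoring sessions
#'
#' Draws a session record for each row of `profiles` from a Gaussian copula
#' over the session channels (distances, counts, Player Load, heart-rate
#' fraction, RPE, duration) with marginals set by session type. RPE is
#' shifted upward with the latent fatigue level; heart-rate fields respect
#' the athlete's individual resting/maximal range.
#'
#' @param profiles one-row (or multi-row) athlete tibble as from
#'   [generate_cohort()].
#' @param day a single row of [generate_calendar()] (must not be a rest day),
#'   or the string `"training"` / `"match"`.
#' @param state a [latent_state()] (scalar fatigue applied to all rows) or a
#'   numeric vector of per-row fatigue levels.
#' @param seed optional seed.
#' @param config session block of [sim_config()].
#' @param f_ref latent reference level subtracted before the RPE shift.
#' @param noise_scale multiplier on all marginal SDs (0 gives mean sessions).
#' @param position_multipliers optional named list of per-position channel
#'   multipliers (already normalised); default applies none.
#' @param phase_scale volume scaling for the calendar phase (default 1).
#' @return A tibble of session records (one per profile row).
#' @export
simulate_session <- function(profiles, day, state,
                             seed = NULL,
                             config = sim_config()$session,
                             f_ref = 0,
                             noise_scale = 1,
                             position_multipliers = NULL,
                             phase_scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  type <- if (is.character(day)) day else as.character(day$day_type)
  if (identical(type, "rest")) abort("cannot simulate a session on a rest day.")
  type <- match.arg(type, c("training", "match"))
  col <- if (type == "training") "train" else "match"
  f <- if (inherits(state, "latent_state")) state$fatigue_level else state
  n <- nrow(profiles)
  f <- rep_len(f, n)

  R <- config$copula_correlation
  ch <- colnames(R)
  Z <- matrix(rnorm(n * length(ch)), n) %*% chol(R)
  colnames(Z) <- ch
  draw <- function(name) {
    m <- config$marginals[[name]][[col]]
    m[1] + m[2] * Z[, name] * noise_scale
  }

  mult <- function(name) {
    if (is.null(position_multipliers) || is.null(position_multipliers[[name]]))
      return(rep(1, n))
    position_multipliers[[name]][as.character(profiles$position)]
  }

  td <- pmax(300, draw("total_distance") * mult("total_distance") * phase_scale)
  hsr <- pmax(0, draw("hsr_distance") * mult("hsr_distance") * phase_scale)
  hsr <- pmin(hsr, 0.30 * td)
  spr <- pmax(0, draw("sprint_distance") * mult("sprint_distance") * phase_scale)
  spr <- pmin(spr, hsr)
  pks <- pmin(37.5, pmax(15, draw("peak_speed")))
  pl <- pmax(40, draw("player_load") * phase_scale)
  acc <- pmax(0, round(draw("accel_count") * mult("accel_count") * phase_scale))
  dec <- pmax(0, round(draw("decel_count") * mult("decel_count") * phase_scale))
  hrf <- pmin(0.95, pmax(0.25, draw("hr_frac")))
  dur <- pmin(180, pmax(40, draw("duration")))
  rpe_raw <- draw("rpe") + config$rpe_fatigue_gain * (f - f_ref)
  rpe <- pmin(10L, pmax(0L, as.integer(round(rpe_raw))))

  hr_mean <- profiles$hr_rest + hrf * (profiles$hr_max - profiles$hr_rest)
  pf <- config$peak_frac[[col]]
  pfrac <- pmin(0.995, pmax(0.05, rnorm(n, pf[1], pf[2] * noise_scale)))
  hr_peak <- hr_mean + pfrac * (profiles$hr_max - hr_mean)

  zones <- t(vapply(seq_len(n), function(i) {
    allocate_zone_minutes(dur[i], hr_mean[i], profiles$hr_max[i],
                          spread = config$zone_spread,
                          in_fraction = config$zone_in_fraction)
  }, numeric(5)))

  hrr1 <- rnorm(n, config$hrr1["mean"], config$hrr1["sd"] * noise_scale) -
    0.5 * (f - f_ref)
  hrr2 <- hrr1 + pmax(0, rnorm(n, config$hrr2_extra["mean"],
                               config$hrr2_extra["sd"] * noise_scale))

  tibble(
    athlete_id = profiles$athlete_id,
    session_type = type,
    duration = round(dur, 1),
    total_distance = round(td),
    hsr_distance = round(hsr),
    sprint_distance = round(spr),
    peak_speed = round(pks, 1),
    rel_distance = round(td / dur, 1),
    accel_count = as.integer(acc),
    decel_count = as.integer(dec),
    player_load = round(pl, 1),
    hr_mean = round(hr_mean, 1),
    hr_peak = round(pmin(hr_peak, profiles$hr_max), 1),
    zone1_min = zones[, 1], zone2_min = zones[, 2], zone3_min = zones[, 3],
    zone4_min = zones[, 4], zone5_min = zones[, 5],
    hrr_1min = round(hrr1, 1),
    hrr_2min = round(hrr2, 1),
    rpe = rpe
  )
}

# parametric allocation of session minutes to the five %HRmax zones
allocate_zone_minutes <- function(duration, hr_mean, hr_max, spread = 9,
                                  in_fraction = 0.92) {
  centers <- c(55, 65, 75, 85, 95)
  pct <- hr_mean / hr_max * 100
  w <- dnorm(centers, mean = pct, sd = spread)
  if (sum(w) <= 0) w <- rep(1, 5)
  mins <- floor(duration * in_fraction * w / sum(w))
  # guard the conservation invariant after rounding
  over <- sum(mins) - floor(duration)
  if (over > 0) mins[which.max(mins)] <- mins[which.max(mins)] - over
  mins
}

#' Simulate a morning monitoring record
#'
#' Morning LnRMSSD falls with the latent fatigue level and with the previous
#' day's load (acute autonomic response); resting heart rate rises with
#' fatigue; the five wellness items (fatigue, sleep, soreness, stress, mood)
#' decline with fatigue and share a common day-level recovery shock with the
#' HRV channel so that criterion hits co-occur realistically.
#'
#' @param profiles athlete tibble rows.
#' @param state [latent_state()] or numeric fatigue vector.
#' @param seed optional seed.
#' @param config morning block of [sim_config()].
#' @param prev_day_load previous-day TRIMP (AU), recycled over rows.
#' @param f_ref,load_ref reference levels subtracted from the latent state
#'   and previous-day load before applying the couplings (defaults 0 give
#'   the plain impulse-response form).
#' @param noise_scale multiplier on all noise terms (0 gives deterministic
#'   expectations).
#' @return A tibble with resting HR, RMSSD, LnRMSSD, the five wellness items
#'   and their total.
#' @export
simulate_morning <- function(profiles, state, seed = NULL,
                             config = sim_config()$morning,
                             prev_day_load = 0,
                             f_ref = 0, load_ref = 0,
                             noise_scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  f <- if (inherits(state, "latent_state")) state$fatigue_level else state
  n <- nrow(profiles)
  f <- rep_len(f, n)
  load <- rep_len(prev_day_load, n)
  fdev <- f - f_ref
  ldev <- (load - load_ref) / 100
  # day-level recovery structure: a latent "poor recovery day" indicator
  # (odds rising with fatigue and the previous day's load) shifts both the
  # HRV and wellness channels, but each channel realises its own shock so
  # the depth of one marker does not determine the depth of the other
  bd <- config$bad_day
  if (!is.null(bd)) {
    p_bad <- stats::plogis(stats::qlogis(bd$base_prob) +
                             bd$f_gain * fdev + bd$load_gain * ldev)
    bad <- runif(n) < p_bad
    shock_h <- rnorm(n) + bad * rnorm(n, bd$shift, bd$sd)
    shock_w <- rnorm(n) + bad * rnorm(n, bd$shift, bd$sd)
  } else {
    shock_h <- shock_w <- rnorm(n)
  }
  shock_h <- shock_h * noise_scale
  shock_w <- shock_w * noise_scale

  lnrmssd <- profiles$lnrmssd_baseline -
    config$beta_hrv * fdev -
    config$beta_hrv_acute * ldev -
    config$hrv_shock * shock_h +
    rnorm(n, 0, config$hrv_noise) * noise_scale
  resting_hr <- profiles$hr_rest + config$rhr_gain * fdev +
    rnorm(n, 0, config$rhr_noise) * noise_scale

  base <- profiles$wellness_base %||% rep(config$wellness_item_base["mean"], n)
  item_mu <- base - config$wellness_delta * fdev -
    config$wellness_delta_acute * ldev - config$wellness_shock * shock_w
  items <- vapply(1:5, function(k) {
    pmin(5L, pmax(1L, as.integer(round(
      item_mu + rnorm(n, 0, config$wellness_noise) * noise_scale
    ))))
  }, integer(n))
  if (n == 1) items <- matrix(items, nrow = 1)

  tibble(
    athlete_id = profiles$athlete_id,
    resting_hr = round(resting_hr, 1),
    rmssd = round(exp(lnrmssd), 1),
    lnrmssd = round(lnrmssd, 3),
    wellness_fatigue = items[, 1],
    wellness_sleep = items[, 2],
    wellness_soreness = items[, 3],
    wellness_stress = items[, 4],
    wellness_mood = items[, 5],
    wellness_total = as.integer(rowSums(items))
  )
}

#' Simulate a weekly neuromuscular test
#'
#' Countermovement-jump height declines proportionally with the latent
#' fatigue level (`cmj = baseline * (1 - beta_cmj * F) + noise`); the 10 m
#' sprint time lengthens correspondingly. Peak power scales with jump height.
#'
#' @inheritParams simulate_morning
#' @param config weekly-test block of [sim_config()].
#' @return A tibble with `cmj_height` (cm), `cmj_peak_power` (W) and
#'   `sprint10` (s).
#' @export
simulate_weekly_test <- function(profiles, state, seed = NULL,
                                 config = sim_config()$weekly_test,
                                 noise_scale = 1) {
  if (!is.null(seed)) set.seed(seed)
  f <- if (inherits(state, "latent_state")) state$fatigue_level else state
  n <- nrow(profiles)
  f <- rep_len(f, n)
  cmj <- profiles$cmj_baseline * (1 - config$beta_cmj * f) +
    rnorm(n, 0, config$cmj_noise) * noise_scale
  cmj <- pmax(8, cmj)
  sprint10 <- profiles$sprint10_baseline * (1 + config$beta_sprint * f) +
    rnorm(n, 0, config$sprint_noise) * noise_scale
  power <- config$power_per_cm * cmj + rnorm(n, 0, config$power_noise) * noise_scale
  tibble(
    athlete_id = profiles$athlete_id,
    cmj_height = round(cmj, 1),
    cmj_peak_power = round(power),
    sprint10 = round(pmax(1.2, sprint10), 3)
  )
}

#' Blank cells completely at random
#'
#' Applies a missing-completely-at-random mask to the measurement columns of
#' each table (identifier and calendar columns are never blanked).
#'
#' @param tables named list of tibbles (`sessions`, `morning`, `tests`, ...).
#' @param rates named list of per-table missing rates in `[0, 1)`; tables
#'   without an entry are left untouched.
#' @param seed optional seed.
#' @return The list of tables with `NA`s inserted.
#' @export
apply_missingness <- function(tables, rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(unlist(rates) < 0 | unlist(rates) >= 1))
    abort("missingness rates must lie in [0, 1).")
  keep <- c("athlete_id", "day_index", "session_type", "day_type",
            "week_index", "phase", "is_test_day", "position")
  for (nm in intersect(names(tables), names(rates))) {
    rate <- rates[[nm]]
    if (rate == 0) next
    tab <- tables[[nm]]
    cols <- setdiff(names(tab), keep)
    for (cl in cols) {
      mask <- runif(nrow(tab)) < rate
      tab[[cl]][mask] <- NA
    }
    tables[[nm]] <- tab
  }
  tables
}

#' Simulate a full monitoring cohort
#'
#' Runs the day-by-day generator: every athlete carries a latent
#' fitness-fatigue state updated each evening with that day's TRIMP; mornings
#' produce HRV/wellness records (before training), Mondays produce weekly
#' CMJ/sprint tests, and scheduled training or match days produce session
#' records (training attendance is Bernoulli per athlete). Missingness is
#' applied last, completely at random, at the configured rates.
#'
#' @param config full simulation configuration, see [sim_config()].
#' @param seed integer seed controlling all randomness.
#' @param missingness apply the configured MCAR mask (default `TRUE`).
#' @return A named list of tibbles: `athletes`, `calendar`, `sessions`,
#'   `morning`, `tests`.
#' @export
#' @examples
#' \donttest{
#' dat <- simulate_monitoring_data(seed = 1)
#' nrow(dat$morning)
#' }
simulate_monitoring_data <- function(config = sim_config(), seed = 1L,
                                     missingness = TRUE) {
  set.seed(seed)
  athletes <- generate_cohort(config$cohort$n_athletes,
                              config$cohort$position_mix,
                              seed = NULL, config = config$cohort)
  calendar <- generate_calendar(config$calendar$weeks, config$calendar$matches)
  scale <- phase_load_scale(calendar)
  pm <- lapply(config$session$position_multipliers, normalise_multipliers,
               positions = athletes$position)
  n <- nrow(athletes)
  tau <- config$latent$decay_tau
  kappa <- config$latent$gain_kappa
  f <- rep(0, n)
  prev_load <- rep(0, n)
  sessions <- vector("list", nrow(calendar))
  mornings <- vector("list", nrow(calendar))
  tests <- vector("list", nrow(calendar))

  for (i in seq_len(nrow(calendar))) {
    day <- calendar[i, ]
    mornings[[i]] <- simulate_morning(
      athletes, f, config = config$morning, prev_day_load = prev_load,
      f_ref = config$latent$f_ref, load_ref = config$latent$load_ref
    ) %>% mutate(day_index = day$day_index, .after = athlete_id)
    if (day$is_test_day) {
      tests[[i]] <- simulate_weekly_test(athletes, f,
                                         config = config$weekly_test) %>%
        mutate(day_index = day$day_index, .after = athlete_id)
    }
    today_load <- rep(0, n)
    if (day$day_type != "rest") {
      present <- if (day$day_type == "match") rep(TRUE, n) else
        runif(n) < athletes$attendance_rate
      if (any(present)) {
        ses <- simulate_session(athletes[present, ], day, f[present],
                                config = config$session,
                                f_ref = config$latent$f_ref,
                                position_multipliers = pm,
                                phase_scale = scale[i]) %>%
          mutate(day_index = day$day_index, .after = athlete_id)
        sessions[[i]] <- ses
        today_load[present] <- compute_trimp(ses$duration, ses$hr_mean,
                                             athletes$hr_rest[present],
                                             athletes$hr_max[present])
      }
    }
    f <- f * exp(-1 / tau) + kappa * today_load / 100
    prev_load <- today_load
  }

  out <- list(
    athletes = athletes,
    calendar = calendar,
    sessions = bind_rows(sessions),
    morning = bind_rows(mornings),
    tests = bind_rows(tests)
  )
  if (missingness) {
    out[c("sessions", "morning", "tests")] <- apply_missingness(
      out[c("sessions", "morning", "tests")], config$missingness
    )
  }
  out
}

#' Toy tri-axial accelerometer trace
#'
#' A short synthetic 100 Hz trace (gravity plus band-limited movement noise)
#' used to exercise the Player Load accumulation formula; the generator does
#' not emit raw accelerometry as a primary output.
#'
#' @param seconds trace length in seconds.
#' @param hz sampling frequency.
#' @param intensity movement noise SD in g.
#' @param seed optional seed.
#' @return A tibble with columns `ax`, `ay`, `az` in g.
#' @export
simulate_accel_trace <- function(seconds = 10, hz = 100, intensity = 0.3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(seconds * hz)
  smooth <- function(x) stats::filter(x, rep(1 / 5, 5), sides = 2) %>%
    as.numeric() %>% tidyr::replace_na(0)
  tibble(
    ax = smooth(rnorm(n, 0, intensity)),
    ay = smooth(rnorm(n, 0, intensity)),
    az = smooth(rnorm(n, 1, intensity))  # gravity on z
  )
}
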