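#' Default simulation configuration
#'
#' Returns the nested list of constants that drives the synthetic
#' monitoring-cohort generator: cohort marginals, calendar layout, session
#' marginals for training vs match days, the Gaussian-copula target
#' correlation matrix, latent fitness-fatigue dynamics, marker couplings and
#' missingness rates. Every constant is a config entry so that the generator
#' can be re-calibrated without touching code; the shipped defaults are
#' calibrated once against published collegiate-soccer load distributions and
#' correlation structure (see the methods vignette).
#'
#' @return A named list. See the methods vignette for the meaning and units
#'   of each entry.
#' @export
#' @examples
#' cfg <- sim_config()
#' names(cfg)
sim_config <- function() {
  list(
    cohort = list(
      n_athletes = 48L,
      # GK/DF/MF/FW head-counts for the default squad
      position_mix = c(GK = 3L, DF = 15L, MF = 18L, FW = 12L),
      hr_max = c(mean = 196.4, sd = 7.3),
      hr_rest = c(mean = 58.2, sd = 6.1),
      cmj_baseline = c(mean = 38.6, sd = 4.2),
      lnrmssd_baseline = c(mean = 4.18, sd = 0.22),
      sprint10_baseline = c(mean = 1.78, sd = 0.08),
      attendance_rate = c(mean = 0.95, sd = 0.04)
    ),
    calendar = list(
      weeks = 12L,
      matches = 24L,
      progressive_weeks = 1:4,
      taper_weeks = 11:12
    ),
    session = list(
      # Marginal means/SDs per session type; columns train/match
      marginals = list(
        total_distance  = list(train = c(5765, 1124), match = c(9847, 1356)),
        hsr_distance    = list(train = c(412, 156),   match = c(876, 203)),
        sprint_distance = list(train = c(98, 45),     match = c(245, 78)),
        peak_speed      = list(train = c(26.3, 2.4),  match = c(29.1, 2.1)),
        player_load     = list(train = c(486, 112),   match = c(892, 145)),
        accel_count     = list(train = c(42, 15),     match = c(78, 22)),
        decel_count     = list(train = c(38, 14),     match = c(71, 19)),
        # fraction of heart-rate reserve sustained over the session
        hr_frac         = list(train = c(0.606, 0.087), match = c(0.744, 0.072)),
        rpe             = list(train = c(3.98, 1.14),  match = c(6.44, 1.55)),
        duration        = list(train = c(95, 15),      match = c(95, 8))
      ),
      # session HR peak as a fraction of the remaining reserve above hr_mean
      peak_frac = list(train = c(0.74, 0.12), match = c(0.90, 0.06)),
      copula_correlation = session_copula_matrix(),
      # multiplicative position factors (normalised to the squad mix at draw
      # time so cohort-level marginals are preserved)
      position_multipliers = list(
        total_distance  = c(GK = 0.70, DF = 0.965, MF = 1.065, FW = 1.000),
        hsr_distance    = c(GK = 0.35, DF = 0.92,  MF = 1.00,  FW = 1.18),
        sprint_distance = c(GK = 0.30, DF = 0.90,  MF = 0.95,  FW = 1.31),
        accel_count     = c(GK = 0.60, DF = 1.05,  MF = 1.00,  FW = 1.05),
        decel_count     = c(GK = 0.55, DF = 1.18,  MF = 1.02,  FW = 0.95)
      ),
      # latent-fatigue shift on session RPE (points per latent unit above ref)
      rpe_fatigue_gain = 0.25,
      hrr1 = c(mean = 28, sd = 6),
      hrr2_extra = c(mean = 22, sd = 5),
      zone_spread = 9,          # %HRmax spread of within-session HR minutes
      zone_in_fraction = 0.92   # share of minutes spent above the 50% floor
    ),
    latent = list(
      decay_tau = 5,     # days
      gain_kappa = 0.8,  # per 100 AU of daily TRIMP
      f_ref = 5.4,       # long-run latent level under the default schedule
      load_ref = 124     # long-run mean daily TRIMP (AU)
    ),
    morning = list(
      beta_hrv = 0.18,        # LnRMSSD drop per latent unit
      beta_hrv_acute = 0.31,  # LnRMSSD drop per 100 AU of previous-day TRIMP
      hrv_shock = 0.36,       # day-level recovery shock loading on LnRMSSD
      hrv_noise = 0.18,
      rhr_gain = 0.8,         # resting-HR rise per latent unit
      rhr_noise = 2.5,
      wellness_item_base = c(mean = 3.95, sd = 0.28),
      wellness_delta = 0.12,        # item drop per latent unit above ref
      wellness_delta_acute = 0.30,  # item drop per 100 AU prev-day TRIMP
      wellness_shock = 0.35,        # day-level recovery shock per item
      wellness_noise = 0.60,
      # mixture "poor recovery" state shared by the HRV and wellness
      # channels; its probability rises with latent fatigue and with the
      # previous day's load, which concentrates criterion co-occurrence on
      # days after heavy sessions and matches
      bad_day = list(base_prob = 0.66, f_gain = 0.70, load_gain = 0.55,
                     shift = 2.8, sd = 0.6)
    ),
    weekly_test = list(
      beta_cmj = 0.02,      # fractional CMJ loss per latent unit
      cmj_noise = 0.9,      # cm
      beta_sprint = 0.012,  # fractional 10 m time gain per latent unit
      sprint_noise = 0.03,  # s
      power_per_cm = 85,    # CMJ peak power scaling (W per cm)
      power_noise = 180     # W
    ),
    missingness = list(
      sessions = 0.054,
      morning = 0.054,
      tests = 0.054
    )
  )
}

#' Target correlation matrix for the session copula
#'
#' The generator specifies pairwise dependence between the session channels
#' on the latent-normal scale; the matrix below was calibrated once so that
#' the *observed* session-level correlations of the generated tables (which
#' pool training and match sessions and include derived TRIMP/sRPE) land on
#' the published heat-map values. Repaired to the nearest positive-definite
#' matrix if rounding makes it indefinite.
#'
#' @return A 10 x 10 named correlation matrix.
#' @keywords internal
session_copula_matrix <- function() {
  ch <- c("total_distance", "hsr_distance", "sprint_distance", "peak_speed",
          "player_load", "accel_count", "decel_count", "hr_frac", "rpe",
          "duration")
  R <- diag(length(ch))
  dimnames(R) <- list(ch, ch)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("total_distance", "hsr_distance", 0.62)
  set_r("total_distance", "sprint_distance", 0.50)
  set_r("total_distance", "peak_speed", 0.35)
  set_r("total_distance", "player_load", 0.89)
  set_r("total_distance", "accel_count", 0.55)
  set_r("total_distance", "decel_count", 0.55)
  set_r("total_distance", "hr_frac", 0.67)
  set_r("total_distance", "rpe", 0.52)
  set_r("total_distance", "duration", 0.60)
  set_r("hsr_distance", "sprint_distance", 0.55)
  set_r("hsr_distance", "peak_speed", 0.55)
  set_r("hsr_distance", "player_load", 0.60)
  set_r("hsr_distance", "accel_count", 0.45)
  set_r("hsr_distance", "decel_count", 0.40)
  set_r("hsr_distance", "hr_frac", 0.40)
  set_r("hsr_distance", "rpe", 0.40)
  set_r("hsr_distance", "duration", 0.25)
  set_r("sprint_distance", "peak_speed", 0.60)
  set_r("sprint_distance", "player_load", 0.50)
  set_r("sprint_distance", "accel_count", 0.40)
  set_r("sprint_distance", "decel_count", 0.35)
  set_r("sprint_distance", "hr_frac", 0.35)
  set_r("sprint_distance", "rpe", 0.35)
  set_r("sprint_distance", "duration", 0.20)
  set_r("peak_speed", "player_load", 0.35)
  set_r("peak_speed", "accel_count", 0.25)
  set_r("peak_speed", "decel_count", 0.25)
  set_r("peak_speed", "hr_frac", 0.25)
  set_r("peak_speed", "rpe", 0.25)
  set_r("peak_speed", "duration", 0.10)
  set_r("player_load", "accel_count", 0.60)
  set_r("player_load", "decel_count", 0.60)
  set_r("player_load", "hr_frac", 0.73)
  set_r("player_load", "rpe", 0.50)
  set_r("player_load", "duration", 0.55)
  set_r("accel_count", "decel_count", 0.80)
  set_r("accel_count", "hr_frac", 0.40)
  set_r("accel_count", "rpe", 0.35)
  set_r("accel_count", "duration", 0.30)
  set_r("decel_count", "hr_frac", 0.40)
  set_r("decel_count", "rpe", 0.35)
  set_r("decel_count", "duration", 0.30)
  set_r("hr_frac", "rpe", 0.55)
  set_r("hr_frac", "duration", 0.38)
  set_r("rpe", "duration", 0.00)
  nearest_pd(R)
}

#' Nearest positive-definite correlation matrix
#'
#' Higham-style eigenvalue clipping with re-normalisation to unit diagonal,
#' iterated until the smallest eigenvalue clears a small floor.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eps smallest admissible eigenvalue.
#' @return A positive-definite correlation matrix of the same dimension.
#' @keywords internal
nearest_pd <- function(R, eps = 1e-8) {
  R <- (R + t(R)) / 2
  for (i in 1:100) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) > eps) break
    vals <- pmax(e$values, eps * 10)
    R <- e$vectors %*% diag(vals) %*% t(e$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    R <- (R + t(R)) / 2
  }
  diag(R) <- 1
  R
}

#' Fatigue-criteria configuration
#'
#' Thresholds for the four-criterion operational fatigue definition and the
#' joint determination rule (fatigued when at least `min_criteria` of the
#' evaluable criteria are met; a day with fewer than `min_evaluable`
#' evaluable criteria is left unlabelled).
#'
#' @param cmj_drop_threshold fractional CMJ height drop vs the individual
#'   rolling test baseline that flags the neuromuscular criterion
#'   (strict `>`; default 0.10).
#' @param lnrmssd_drop_threshold absolute LnRMSSD drop vs the individual
#'   7-day rolling baseline (strict `>`; default 0.5).
#' @param wellness_threshold wellness total below which the subjective
#'   criterion is met (strict `<`; default 15 points of 25).
#' @param rpe_threshold session-RPE level counting toward the perceived
#'   exertion criterion (`>=`; default 8).
#' @param rpe_consecutive_days number of consecutive session days at or above
#'   `rpe_threshold` (default 2).
#' @param min_criteria criteria that must be met jointly (default 2).
#' @param min_evaluable minimum evaluable criteria for a day to be labelled
#'   (default 2).
#' @param cmj_carry_days days a weekly CMJ evaluation is carried forward
#'   (default 6).
#' @param cmj_baseline_tests maximum number of prior weekly tests averaged
#'   into the CMJ baseline (default 4).
#' @param hrv_window,hrv_min_obs rolling window (days) and minimum prior
#'   observations for the LnRMSSD baseline.
#' @return A list of class `fatigue_criteria`.
#' @export
fatigue_criteria <- function(cmj_drop_threshold = 0.10,
                             lnrmssd_drop_threshold = 0.5,
                             wellness_threshold = 15,
                             rpe_threshold = 8,
                             rpe_consecutive_days = 2L,
                             min_criteria = 2L,
                             min_evaluable = 2L,
                             cmj_carry_days = 6L,
                             cmj_baseline_tests = 4L,
                             hrv_window = 7L,
                             hrv_min_obs = 3L) {
  stopifnot(cmj_drop_threshold > 0, lnrmssd_drop_threshold > 0,
            wellness_threshold > 0, rpe_threshold > 0,
            min_criteria >= 1, min_criteria <= 4, min_evaluable >= 1)
  structure(
    list(cmj_drop_threshold = cmj_drop_threshold,
         lnrmssd_drop_threshold = lnrmssd_drop_threshold,
         wellness_threshold = wellness_threshold,
         rpe_threshold = rpe_threshold,
         rpe_consecutive_days = as.integer(rpe_consecutive_days),
         min_criteria = as.integer(min_criteria),
         min_evaluable = as.integer(min_evaluable),
         cmj_carry_days = as.integer(cmj_carry_days),
         cmj_baseline_tests = as.integer(cmj_baseline_tests),
         hrv_window = as.integer(hrv_window),
         hrv_min_obs = as.integer(hrv_min_obs)),
    class = "fatigue_criteria"
  )
}

#' Read / write a run configuration as YAML
#'
#' The whole pipeline is driven by one serialisable configuration: the
#' simulation constants from [sim_config()], the criteria thresholds from
#' [fatigue_criteria()], the daily-load stream feeding ACWR/monotony/strain
#' and the model harness settings.
#'
#' @param path file path of a YAML configuration.
#' @return `read_run_config()` returns a validated configuration list;
#'   `write_run_config()` writes it and returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- run_config()
  cfg <- utils::modifyList(base, cfg)
  # matrices survive YAML as row lists; restore
  cc <- cfg$simulate$session$copula_correlation
  if (is.list(cc)) {
    cfg$simulate$session$copula_correlation <-
      nearest_pd(do.call(rbind, lapply(cc, unlist)))
  }
  cfg$criteria <- do.call(fatigue_criteria, cfg$criteria)
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config a run configuration list, as from [run_config()].
#' @export
write_run_config <- function(config, path) {
  config$criteria <- unclass(config$criteria)
  cc <- config$simulate$session$copula_correlation
  config$simulate$session$copula_correlation <-
    apply(cc, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default end-to-end run configuration
#'
#' @param seed integer seed recorded in the manifest and used for every
#'   source of randomness in the pipeline.
#' @return A named list combining simulation, indicator, labelling and model
#'   settings.
#' @export
run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = sim_config(),
    load_metric = "srpe",        # daily-load stream for ACWR/monotony/strain
    criteria = fatigue_criteria(),
    models = list(
      kinds = c("dummy_stratified", "logistic_l2", "random_forest", "xgboost"),
      schemes = c("stratified_10fold"),
      loso_for = "xgboost",
      single_indicator = c("srpe_only", "acwr_only", "wellness_only"),
      dummy_reps = 100L
    )
  )
}

#' Validate a run configuration
#'
#' Checks the structural invariants of a [run_config()] list (cohort size
#' and mix, missingness rates, load stream, criteria object) and errors on
#' the first violation.
#'
#' @param cfg a run configuration list.
#' @return The configuration, invisibly, when valid.
#' @export
validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$seed)) abort("`seed` must be an integer.")
  sim <- cfg$simulate
  if (sim$cohort$n_athletes < 4) abort("cohort: need at least 4 athletes.")
  if (sum(sim$cohort$position_mix) != sim$cohort$n_athletes)
    abort("cohort: position_mix must sum to n_athletes.")
  rates <- unlist(sim$missingness)
  if (any(rates < 0 | rates >= 1)) abort("missingness rates must lie in [0, 1).")
  if (!cfg$load_metric %in% c("srpe", "trimp"))
    abort("load_metric must be 'srpe' or 'trimp'.")
  if (!inherits(cfg$criteria, "fatigue_criteria"))
    abort("criteria must be a fatigue_criteria() object.")
  invisible(cfg)
}
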