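#' Flag 3-SD outliers
#'
#' Flags values deviating more than three standard deviations from the mean
#' (mean and SD over the non-missing values). Constant columns yield no
#' flags.
#'
#' @param x numeric vector (at least 3 non-missing values to flag anything).
#' @return Logical vector, `TRUE` where `|x - mean| > 3 * sd`; `NA` inputs
#'   are `FALSE`.
#' @export
#' @examples
#' flag_outliers(c(rnorm(50), 10))
flag_outliers <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 3) return(rep(FALSE, length(x)))
  m <- mean(x[ok])
  s <- sd(x[ok])
  if (is.na(s) || s == 0) return(rep(FALSE, length(x)))
  out <- abs(x - m) > 3 * s
  out[!out | is.na(out)] <- FALSE
  out
}

#' Remove flagged outliers from a table
#'
#' Applies [flag_outliers()] per numeric variable — per athlete where an
#' athlete has at least `min_per_athlete` observations of that variable,
#' otherwise across the cohort — and sets flagged cells to `NA`.
#'
#' @param table tibble with an `athlete_id` column.
#' @param vars character vector of columns to screen; default all numeric
#'   measurement columns.
#' @param min_per_athlete observations required for the per-athlete rule.
#' @return List with the cleaned `table` and `n_flagged` per variable.
#' @export
screen_outliers <- function(table, vars = NULL, min_per_athlete = 20) {
  if (is.null(vars)) {
    vars <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                    c("day_index", "week_index"))
  }
  n_flagged <- setNames(integer(length(vars)), vars)
  for (v in vars) {
    per_athlete <- table %>%
      group_by(athlete_id) %>%
      mutate(.n_obs = sum(!is.na(.data[[v]]))) %>%
      ungroup()
    big <- per_athlete$.n_obs >= min_per_athlete
    flags <- rep(FALSE, nrow(table))
    if (any(big)) {
      flags[big] <- stats::ave(table[[v]][big], table$athlete_id[big],
                               FUN = function(z) as.numeric(flag_outliers(z))) == 1
    }
    if (any(!big)) flags[!big] <- flag_outliers(table[[v]][!big])
    n_flagged[v] <- sum(flags, na.rm = TRUE)
    table[[v]][flags] <- NA
  }
  list(table = table, n_flagged = n_flagged)
}

#' Tiered missing-value imputation
#'
#' Variables with a missing rate below `mean_tier` are mean-imputed within
#' athlete (falling back to the cohort mean); variables between `mean_tier`
#' and `exclude_tier` are imputed by chained stochastic regression on the
#' other numeric variables, with `m` completed draws averaged into the
#' returned table; athletes missing more than `exclude_tier` of their cells
#' are dropped and reported.
#'
#' @param table tibble with `athlete_id` and numeric measurement columns.
#' @param vars columns to impute; default all numeric except day/week keys.
#' @param mean_tier,exclude_tier tier boundaries (defaults 0.05 and 0.20).
#' @param m number of stochastic-regression draws averaged (default 5).
#' @param seed optional seed.
#' @return List with the completed `table` and a `report` tibble
#'   (per-variable missing rate and tier) plus `excluded_athletes`.
#' @export
impute_missing <- function(table, vars = NULL, mean_tier = 0.05,
                           exclude_tier = 0.20, m = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(vars)) {
    vars <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                    c("day_index", "week_index"))
  }
  athlete_rate <- table %>%
    group_by(athlete_id) %>%
    summarise(rate = mean(is.na(dplyr::pick(dplyr::all_of(vars)))),
              .groups = "drop")
  excluded <- athlete_rate$athlete_id[athlete_rate$rate > exclude_tier]
  table <- filter(table, !athlete_id %in% excluded)

  rates <- vapply(vars, function(v) mean(is.na(table[[v]])), numeric(1))
  tier <- ifelse(rates == 0, "none",
                 ifelse(rates < mean_tier, "mean",
                        ifelse(rates <= exclude_tier, "multiple", "drop")))
  report <- tibble(variable = vars, missing_rate = unname(rates),
                   tier = unname(tier))
  if (any(rates == 1)) abort(paste("variable fully missing:",
                                   paste(vars[rates == 1], collapse = ", ")))

  mean_vars <- vars[tier == "mean"]
  for (v in mean_vars) {
    table <- table %>%
      group_by(athlete_id) %>%
      mutate(!!v := ifelse(is.na(.data[[v]]),
                           mean(.data[[v]], na.rm = TRUE), .data[[v]])) %>%
      ungroup()
    table[[v]][is.nan(table[[v]])] <- mean(table[[v]], na.rm = TRUE)
    table[[v]][is.na(table[[v]])] <- mean(table[[v]], na.rm = TRUE)
  }

  multi_vars <- vars[tier == "multiple"]
  if (length(multi_vars) > 0) {
    preds <- vars
    draws <- lapply(seq_len(m), function(d) {
      chained_stochastic_impute(table, multi_vars, preds)
    })
    for (v in multi_vars) {
      filled <- rowMeans(do.call(cbind, lapply(draws, function(d) d[[v]])))
      miss <- is.na(table[[v]])
      table[[v]][miss] <- filled[miss]
    }
  }
  list(table = table, report = report, excluded_athletes = excluded)
}

# one chained stochastic-regression completion of the target variables
chained_stochastic_impute <- function(table, targets, preds) {
  work <- table[, unique(c(targets, preds)), drop = FALSE]
  # start from marginal mean fills
  for (v in names(work)) {
    miss <- is.na(work[[v]])
    if (any(miss)) work[[v]][miss] <- mean(work[[v]], na.rm = TRUE)
  }
  for (v in targets) {
    miss <- is.na(table[[v]])
    if (!any(miss)) next
    rhs <- setdiff(preds, v)
    # guard against constant predictors
    rhs <- rhs[vapply(rhs, function(p) sd(work[[p]]) > 0, logical(1))]
    if (length(rhs) == 0) next
    fml <- stats::as.formula(paste0("`", v, "` ~ ",
                                    paste0("`", rhs, "`", collapse = " + ")))
    fit_data <- work[!miss, , drop = FALSE]
    fit_data[[v]] <- table[[v]][!miss]
    fit <- lm(fml, data = fit_data)
    sigma <- summary(fit)$sigma
    if (is.na(sigma)) sigma <- 0
    pred <- predict(fit, newdata = work[miss, , drop = FALSE])
    work[[v]][miss] <- pred + rnorm(sum(miss), 0, sigma)
  }
  work[, targets, drop = FALSE]
}

#' Fit / apply z-score standardisation
#'
#' `zscore_fit()` learns per-column means and SDs; `zscore_apply()` applies
#' them to (possibly different) data. Splitting fit from application lets
#' cross-validation standardise test folds with training-fold parameters
#' only.
#'
#' @param data tibble of numeric columns.
#' @param cols columns to standardise (default: all numeric).
#' @return `zscore_fit()`: a list with `center` and `scale`;
#'   `zscore_apply()`: the standardised tibble.
#' @export
#' @examples
#' p <- zscore_fit(tibble::tibble(x = c(1, 2, 3)))
#' zscore_apply(tibble::tibble(x = c(1, 2, 3)), p)
zscore_fit <- function(data, cols = NULL) {
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  center <- vapply(cols, function(v) mean(data[[v]], na.rm = TRUE), numeric(1))
  scale <- vapply(cols, function(v) sd(data[[v]], na.rm = TRUE), numeric(1))
  if (any(scale == 0, na.rm = TRUE))
    abort(paste("zero-variance column:",
                paste(cols[which(scale == 0)], collapse = ", ")))
  list(center = center, scale = scale)
}

#' @rdname zscore_fit
#' @param params a fit from `zscore_fit()`.
#' @export
zscore_apply <- function(data, params) {
  for (v in names(params$center)) {
    data[[v]] <- (data[[v]] - params$center[[v]]) / params$scale[[v]]
  }
  data
}

#' Z-score a numeric vector
#'
#' @param x numeric vector with positive SD.
#' @return `(x - mean) / sd` using the sample SD.
#' @export
zscore <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) abort("zero-variance input.")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Assemble the athlete-day modelling table
#'
#' Inner-joins the morning table with the derived-load table on athlete-day,
#' attaches previous-day load fields (day `t - 1` only), the trailing weekly
#' aggregates, the lag-1 ACWR (the value available on waking), and days
#' since the most recent match. One row per athlete-day with a morning
#' record.
#'
#' @param morning morning tibble.
#' @param derived athlete-day derived-load tibble from [derive_loads()].
#' @param calendar calendar tibble.
#' @return The assembled tibble.
#' @export
assemble_daily_table <- function(morning, derived, calendar) {
  if (anyDuplicated(morning[c("athlete_id", "day_index")]) > 0)
    abort("duplicate athlete-day keys in morning table.")
  lagged <- derived %>%
    arrange(athlete_id, day_index) %>%
    group_by(athlete_id) %>%
    mutate(
      prev_total_distance = lag(total_distance),
      prev_hsr = lag(hsr_distance),
      prev_player_load = lag(player_load),
      prev_trimp = lag(trimp),
      prev_srpe = lag(srpe),
      acwr_lag = lag(acwr)
    ) %>%
    ungroup() %>%
    select(athlete_id, day_index, prev_total_distance, prev_hsr,
           prev_player_load, prev_trimp, prev_srpe, acwr_lag,
           week_monotony, week_strain, weekly_total_distance)

  match_days <- calendar$day_index[calendar$day_type == "match"]
  morning %>%
    select(athlete_id, day_index, resting_hr, lnrmssd, wellness_total) %>%
    inner_join(lagged, by = c("athlete_id", "day_index")) %>%
    rename(acwr = acwr_lag) %>%
    mutate(days_since_match = days_since_event(day_index, match_days)) %>%
    arrange(athlete_id, day_index)
}
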