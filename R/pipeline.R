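#' Run the full monitoring-analysis pipeline
#'
#' Wires the stages end to end: simulate (or load) the monitoring tables,
#' derive the load indicators, label fatigue, assemble and quality-control
#' the athlete-day table, run the model-comparison harness, and render the
#' report tables. Every artefact is written as plain CSV/JSON under
#' `out_dir`; the manifest records the seed and a configuration hash so a
#' run is reproducible bit for bit from `(config, seed)`.
#'
#' @param config a [run_config()] list (or a YAML path readable by
#'   [read_run_config()]).
#' @param out_dir output directory; `NULL` skips writing files.
#' @param stages character subset of
#'   `c("simulate", "indicators", "label", "qc", "train", "report")`.
#'   Later stages re-use in-memory results of earlier ones; running a later
#'   stage alone requires `data` (or `out_dir` with previous artefacts).
#' @param data optional pre-existing list of monitoring tables (replaces
#'   the simulate stage, so real exported data can be analysed).
#' @return A list with `data`, `derived`, `labels`, `assembled`, `qc`,
#'   `features`, `models`, `metrics`, `attribution`, `roc` (stages not run
#'   are `NULL`).
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(run_config(seed = 1), out_dir = NULL,
#'                     stages = c("simulate", "indicators", "label"))
#' res$labels$summary$prevalence_pct
#' }
run_pipeline <- function(config = run_config(), out_dir = "fatiguelab_run",
                         stages = c("simulate", "indicators", "label", "qc",
                                    "train", "report"),
                         data = NULL) {
  if (is.character(config) && length(config) == 1 && file.exists(config))
    config <- read_run_config(config)
  validate_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- config$seed
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  res <- list(config = config)

  if ("simulate" %in% stages && is.null(data)) {
    message("stage simulate: generating cohort (seed ", seed, ")")
    data <- simulate_monitoring_data(config$simulate, seed = seed)
    if (!is.null(out_dir)) {
      readr::write_csv(data$athletes, file.path(out_dir, "athletes.csv"))
      readr::write_csv(data$calendar, file.path(out_dir, "calendar.csv"))
      readr::write_csv(data$sessions, file.path(out_dir, "sessions.csv"))
      readr::write_csv(data$morning, file.path(out_dir, "morning.csv"))
      readr::write_csv(data$tests, file.path(out_dir, "tests.csv"))
    }
  }
  if (is.null(data) && !is.null(out_dir)) data <- read_monitoring_dir(out_dir)
  if (is.null(data)) abort("no monitoring data: run the simulate stage or pass `data`.")
  res$data <- data
  message(sprintf("  %d athletes, %d sessions, %d person-days",
                  nrow(data$athletes), nrow(data$sessions),
                  nrow(data$morning)))

  if ("indicators" %in% stages) {
    message("stage indicators: deriving athlete-day loads")
    res$derived <- derive_loads(data$sessions, data$athletes, data$calendar,
                                load_metric = config$load_metric)
    if (!is.null(out_dir)) {
      out <- res$derived %>%
        mutate(across(c(acute_ewma, chronic_ewma, acwr, week_monotony,
                        week_strain), ~ round(.x, 6)))
      readr::write_csv(out, file.path(out_dir, "derived_loads.csv"))
    }
  }

  if ("label" %in% stages) {
    message("stage label: applying the fatigue criteria")
    res$labels <- label_fatigue(data, config$criteria)
    message(sprintf("  prevalence %.1f%% over %d labelled days",
                    res$labels$summary$prevalence_pct,
                    res$labels$summary$n_labeled))
    if (!is.null(out_dir)) {
      readr::write_csv(res$labels$labels, file.path(out_dir, "labels.csv"))
    }
  }

  if ("qc" %in% stages) {
    if (is.null(res$derived)) abort("qc stage requires the indicators stage.")
    message("stage qc: outlier screen, imputation, assembly")
    assembled <- assemble_daily_table(data$morning, res$derived, data$calendar)
    scr <- screen_outliers(assembled,
                           vars = c("resting_hr", "lnrmssd", "wellness_total"))
    imp <- impute_missing(scr$table, seed = seed)
    res$assembled <- imp$table
    res$qc <- list(n_outliers_flagged = scr$n_flagged,
                   imputation = imp$report,
                   excluded_athletes = imp$excluded_athletes)
    if (!is.null(out_dir)) {
      readr::write_csv(res$assembled, file.path(out_dir, "features.csv"))
      jsonlite::write_json(res$qc, file.path(out_dir, "qc_report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  if ("train" %in% stages) {
    if (is.null(res$assembled) || is.null(res$labels))
      abort("train stage requires the qc and label stages (features.csv/labels.csv).")
    message("stage train: model comparison harness")
    res <- c(res, train_models(res$assembled, res$labels$labels,
                               config$models, seed = seed))
    if (!is.null(out_dir)) {
      readr::write_csv(res$metrics, file.path(out_dir, "metrics.csv"))
      jsonlite::write_json(res$metrics, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      readr::write_csv(res$attribution$importance,
                       file.path(out_dir, "importance.csv"))
      readr::write_csv(res$attribution$shap,
                       file.path(out_dir, "shap_values.csv"))
      readr::write_csv(res$roc$roc, file.path(out_dir, "roc_points.csv"))
    }
  }

  if ("report" %in% stages) {
    if (is.null(res$labels) || is.null(res$assembled) || is.null(res$metrics))
      abort("report stage requires label, qc and train stages.")
    message("stage report: writing summary tables")
    if (!is.null(out_dir)) {
      render_report(res, out_dir, seed = seed,
                    config_hash = config_hash(config))
    }
  }
  invisible(res)
}

#' Stable hash of a run configuration
#'
#' @param config a [run_config()] list.
#' @return A character hash recorded in the run manifest.
#' @export
config_hash <- function(config) rlang::hash(config)

read_monitoring_dir <- function(dir) {
  need <- c("athletes", "calendar", "sessions", "morning", "tests")
  paths <- file.path(dir, paste0(need, ".csv"))
  missing <- need[!file.exists(paths)]
  if (length(missing) > 0)
    abort(paste0("missing input files in ", dir, ": ",
                 paste0(missing, ".csv", collapse = ", ")))
  out <- lapply(paths, readr::read_csv, show_col_types = FALSE)
  names(out) <- need
  out$calendar <- out$calendar %>%
    mutate(day_type = factor(day_type, levels = c("training", "match", "rest")))
  out
}

# the model-comparison block: fused models under 10-fold CV, LOSO for the
# configured model, single-indicator comparators, dummy baseline,
# attribution report and pooled ROC for the best model
train_models <- function(assembled, labels, model_cfg, seed = 1L) {
  full <- build_feature_table(assembled, labels, "full")
  panels <- list()

  dummy <- dummy_baseline(full$y, seed = seed, reps = model_cfg$dummy_reps)
  panels[["dummy"]] <- glance(dummy) %>% mutate(feature_set = "full")

  kinds <- setdiff(model_cfg$kinds, "dummy_stratified")
  fits <- list()
  for (kind in kinds) {
    cv <- run_cv(full$features, full$y, model_spec(kind),
                 scheme = "stratified_10fold", seed = seed)
    panels[[kind]] <- glance(cv) %>% mutate(feature_set = "full")
  }
  if (!is.null(model_cfg$loso_for)) {
    cv <- run_cv(full$features, full$y, model_spec(model_cfg$loso_for),
                 scheme = "loso", groups = full$groups, seed = seed)
    panels[["loso"]] <- glance(cv) %>% mutate(feature_set = "full")
  }
  for (fs in model_cfg$single_indicator) {
    ft <- build_feature_table(assembled, labels, fs)
    cv <- run_cv(ft$features, ft$y, model_spec("xgboost"),
                 scheme = "stratified_10fold", seed = seed)
    panels[[fs]] <- glance(cv) %>% mutate(feature_set = fs)
  }
  metrics <- bind_rows(panels)

  boost <- fit_boosting(full$features, full$y, seed = seed)
  attribution <- attributions(boost, full$features)
  roc <- roc_youden(full$y, predict_boosting(boost, full$features))

  list(features = full, metrics = metrics, attribution = attribution,
       roc = roc, boosting_fit = boost)
}
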