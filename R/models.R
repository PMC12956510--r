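#' Build the modelling feature table
#'
#' Joins labels onto the assembled athlete-day table, drops unlabelable
#' days, and selects the requested feature set: `full` uses the thirteen
#' fused multi-sensor features (wellness total, ACWR, morning LnRMSSD,
#' previous-day sRPE/total distance/Player Load/TRIMP/high-speed distance,
#' trailing weekly total distance, monotony, strain, resting HR, days since
#' match); the single-indicator sets keep exactly one predictor.
#'
#' @param assembled tibble from [assemble_daily_table()].
#' @param labels label tibble from [label_fatigue()].
#' @param feature_set one of `"full"`, `"srpe_only"`, `"acwr_only"`,
#'   `"wellness_only"`.
#' @return A list: `features` (tibble), `y` (integer 0/1), `groups`
#'   (athlete ids).
#' @export
build_feature_table <- function(assembled, labels,
                                feature_set = c("full", "srpe_only",
                                                "acwr_only", "wellness_only")) {
  feature_set <- match.arg(feature_set)
  dat <- assembled %>%
    inner_join(select(labels, athlete_id, day_index, label),
               by = c("athlete_id", "day_index")) %>%
    filter(label != "unlabelable")
  if (nrow(dat) == 0) abort("no labelled rows.")
  cols <- switch(
    feature_set,
    full = c("wellness_total", "acwr", "lnrmssd", "prev_srpe",
             "prev_total_distance", "prev_player_load", "prev_trimp",
             "prev_hsr", "weekly_total_distance", "week_monotony",
             "week_strain", "resting_hr", "days_since_match"),
    srpe_only = "prev_srpe",
    acwr_only = "acwr",
    wellness_only = "wellness_total"
  )
  list(
    features = dat[, cols, drop = FALSE],
    y = as.integer(dat$label == "fatigued"),
    groups = dat$athlete_id
  )
}

#' Model specification
#'
#' Hyperparameters follow the published defaults: ridge-penalised logistic
#' regression at unit inverse-regularisation (glmnet `lambda = 1/n`), random
#' forest with 500 trees and `sqrt(p)` candidate features, gradient boosting
#' with learning rate 0.1, depth 6, 100 rounds, 0.8 row subsampling.
#'
#' @param kind one of `"dummy_stratified"`, `"logistic_l2"`,
#'   `"random_forest"`, `"xgboost"`.
#' @param ... overrides of the default hyperparameters.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("xgboost", "logistic_l2", "random_forest",
                                "dummy_stratified"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(
    kind,
    logistic_l2 = list(C = 1.0),
    random_forest = list(num_trees = 500L),
    xgboost = list(eta = 0.1, max_depth = 6L, nrounds = 100L, subsample = 0.8),
    dummy_stratified = list()
  )
  structure(c(list(kind = kind), utils::modifyList(defaults, list(...))),
            class = "model_spec")
}

# fit a spec on standardized training data; returns a closure scoring new data
fit_model <- function(spec, X, y, seed = 1L) {
  X <- as.matrix(X)
  set.seed(seed)
  switch(
    spec$kind,
    dummy_stratified = {
      p <- mean(y)
      function(newX) as.numeric(runif(nrow(newX)) < p)
    },
    logistic_l2 = {
      if (length(unique(y)) < 2) abort("single-class training fold.")
      # glmnet requires >= 2 columns; a zero pad carries no information
      pad <- ncol(X) == 1
      if (pad) X <- cbind(X, .pad = 0)
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                            lambda = 1 / (nrow(X) * spec$C),
                            standardize = FALSE)
      function(newX) {
        newX <- as.matrix(newX)
        if (pad) newX <- cbind(newX, .pad = 0)
        as.numeric(predict(fit, newX, type = "response"))
      }
    },
    random_forest = {
      df <- as.data.frame(X)
      df$.y <- factor(y, levels = c(0, 1))
      fit <- ranger::ranger(
        .y ~ ., data = df, num.trees = spec$num_trees,
        mtry = max(1L, floor(sqrt(ncol(X)))), probability = TRUE,
        seed = seed, num.threads = 1
      )
      function(newX) {
        predict(fit, as.data.frame(as.matrix(newX)),
                num.threads = 1)$predictions[, "1"]
      }
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = spec$eta,
                      max_depth = spec$max_depth, subsample = spec$subsample,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = spec$nrounds, verbose = 0
      )
      structure(function(newX) {
        predict(fit, xgboost::xgb.DMatrix(as.matrix(newX)))
      }, booster = fit)
    },
    abort(paste("unknown model kind:", spec$kind))
  )
}

# deterministic stratified k-fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(y, k = 10, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated model evaluation
#'
#' Runs the full honest-evaluation loop: within each training fold the
#' preprocessing (mean imputation and z-scoring) is fitted and then applied
#' to the test fold, the model is fitted, and test-fold metrics are
#' computed at the decision threshold. Schemes: stratified 10-fold, or
#' leave-one-subject-out where every athlete's complete data are held out
#' once. Folds whose training data contain a single class are skipped with
#' a warning.
#'
#' @param features tibble of predictors (may contain `NA`s).
#' @param y binary labels.
#' @param spec a [model_spec()].
#' @param scheme `"stratified_10fold"` or `"loso"`.
#' @param groups athlete ids (required for `"loso"`).
#' @param k folds for the stratified scheme.
#' @param seed integer seed controlling fold assignment and model fits.
#' @param threshold decision threshold (default 0.5).
#' @return A `fatigue_cv` object: per-fold metrics with [tidy()] and a
#'   mean +/- SD panel with [glance()] (AUC CI by normal approximation over
#'   folds).
#' @export
#' @examples
#' \donttest{
#' X <- tibble::tibble(a = rnorm(300))
#' y <- rbinom(300, 1, plogis(2 * X$a))
#' glance(run_cv(X, y, model_spec("logistic_l2")))
#' }
run_cv <- function(features, y, spec = model_spec("xgboost"),
                   scheme = c("stratified_10fold", "loso"),
                   groups = NULL, k = 10, seed = 1L, threshold = 0.5) {
  scheme <- match.arg(scheme)
  y <- as_binary_label(y)
  if (scheme == "loso") {
    if (is.null(groups)) abort("loso scheme requires athlete groups.")
    fold_id <- as.integer(factor(groups))
  } else {
    fold_id <- stratified_folds(y, k = k, seed = seed)
  }
  folds <- sort(unique(fold_id))
  rows <- list()
  skipped <- 0L
  for (f in folds) {
    tr <- fold_id != f
    te <- !tr
    if (length(unique(y[tr])) < 2) { skipped <- skipped + 1L; next }
    if (sum(te) == 0) next
    Xtr <- features[tr, , drop = FALSE]
    Xte <- features[te, , drop = FALSE]
    # preprocessing fitted on the training fold only
    fills <- vapply(Xtr, function(x) mean(x, na.rm = TRUE), numeric(1))
    fills[is.na(fills)] <- 0
    for (v in names(fills)) {
      Xtr[[v]][is.na(Xtr[[v]])] <- fills[[v]]
      Xte[[v]][is.na(Xte[[v]])] <- fills[[v]]
    }
    keep <- vapply(Xtr, function(x) sd(x) > 0, logical(1))
    Xtr <- Xtr[, keep, drop = FALSE]
    Xte <- Xte[, keep, drop = FALSE]
    zs <- zscore_fit(Xtr)
    Xtr <- zscore_apply(Xtr, zs)
    Xte <- zscore_apply(Xte, zs)
    scorer <- fit_model(spec, Xtr, y[tr], seed = seed + f)
    sc <- scorer(Xte)
    rows[[length(rows) + 1]] <-
      compute_metrics(y[te], sc, threshold) %>% mutate(fold = f, .before = 1)
  }
  if (skipped > 0)
    warn(sprintf("%d single-class training fold(s) skipped.", skipped))
  if (length(rows) == 0) abort("no usable folds.")
  new_fatigue_cv(bind_rows(rows), model = spec$kind, scheme = scheme,
                 n = length(y))
}

new_fatigue_cv <- function(folds, model, scheme, n) {
  structure(list(folds = folds, model = model, scheme = scheme, n = n),
            class = "fatigue_cv")
}

#' @export
print.fatigue_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<fatigue_cv> %s / %s, %d folds, n = %d\n",
              x$model, x$scheme, nrow(x$folds), x$n))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), accuracy %.3f\n",
              g$auc_mean, g$auc_ci_lo, g$auc_ci_hi, g$accuracy_mean))
  invisible(x)
}

#' Tidy per-fold metrics of a cross-validation run
#'
#' @param x a `fatigue_cv` object.
#' @param ... unused.
#' @return A tibble with one row per fold: accuracy, sensitivity,
#'   specificity, F1, AUC.
#' @export
tidy.fatigue_cv <- function(x, ...) {
  x$folds %>% mutate(model = x$model, scheme = x$scheme, .before = 1)
}

#' One-row performance panel of a cross-validation run
#'
#' Means and SDs over folds, with a normal-approximation 95% CI for the
#' AUC (`mean +/- 1.96 * sd / sqrt(folds)`).
#'
#' @inheritParams tidy.fatigue_cv
#' @return A one-row tibble.
#' @export
glance.fatigue_cv <- function(x, ...) {
  f <- x$folds
  k <- nrow(f)
  msd <- function(v) c(mean(v, na.rm = TRUE), sd(v, na.rm = TRUE))
  a <- msd(f$auc)
  half <- if (k > 1) 1.96 * a[2] / sqrt(k) else 0
  tibble(
    model = x$model, scheme = x$scheme, n_folds = k,
    accuracy_mean = mean(f$accuracy, na.rm = TRUE),
    accuracy_sd = sd(f$accuracy, na.rm = TRUE),
    sensitivity_mean = mean(f$sensitivity, na.rm = TRUE),
    sensitivity_sd = sd(f$sensitivity, na.rm = TRUE),
    specificity_mean = mean(f$specificity, na.rm = TRUE),
    specificity_sd = sd(f$specificity, na.rm = TRUE),
    f1_mean = mean(f$f1, na.rm = TRUE),
    f1_sd = sd(f$f1, na.rm = TRUE),
    auc_mean = a[1], auc_sd = a[2],
    auc_ci_lo = a[1] - half, auc_ci_hi = a[1] + half
  )
}
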