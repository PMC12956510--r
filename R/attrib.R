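#' Fit the gradient-boosting model on the full table
#'
#' Convenience fitter used for attribution analysis (importance and Shapley
#' values are properties of one model fitted to all labelled data, unlike
#' the cross-validated performance panel). Mean imputation and z-scoring are
#' fitted on the same data.
#'
#' @param features predictor tibble.
#' @param y binary labels.
#' @param spec a [model_spec()] of kind `"xgboost"`.
#' @param seed integer seed.
#' @return An object of class `fatigue_boosting` carrying the booster and
#'   the preprocessing parameters.
#' @export
fit_boosting <- function(features, y, spec = model_spec("xgboost"),
                         seed = 1L) {
  if (!identical(spec$kind, "xgboost"))
    abort("fit_boosting requires an xgboost model_spec.")
  y <- as_binary_label(y)
  fills <- vapply(features, function(x) mean(x, na.rm = TRUE), numeric(1))
  fills[is.na(fills)] <- 0
  for (v in names(fills)) features[[v]][is.na(features[[v]])] <- fills[[v]]
  zs <- zscore_fit(features)
  Xs <- as.matrix(zscore_apply(features, zs))
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = spec$eta,
                  max_depth = spec$max_depth, subsample = spec$subsample,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(Xs, label = y),
    nrounds = spec$nrounds, verbose = 0
  )
  structure(list(booster = booster, fills = fills, zscore = zs,
                 feature_names = colnames(Xs)),
            class = "fatigue_boosting")
}

prep_matrix <- function(object, features) {
  for (v in names(object$fills)) {
    if (!v %in% names(features)) abort(paste("missing feature:", v))
    features[[v]][is.na(features[[v]])] <- object$fills[[v]]
  }
  as.matrix(zscore_apply(features[, object$feature_names, drop = FALSE],
                         object$zscore))
}

#' Margin (log-odds) predictions of a fitted boosting model
#'
#' @param object a `fatigue_boosting` fit.
#' @param features predictor tibble on the raw scale.
#' @param type `"margin"` for log-odds or `"response"` for probabilities.
#' @return Numeric vector of predictions.
#' @export
predict_boosting <- function(object, features,
                             type = c("response", "margin")) {
  type <- match.arg(type)
  dm <- xgboost::xgb.DMatrix(prep_matrix(object, features))
  predict(object$booster, dm, outputmargin = type == "margin")
}

#' Importance and exact tree-Shapley attributions
#'
#' Gain-based (impurity) importances of the tree ensemble normalised to
#' percentages, and exact path-dependent TreeSHAP contributions on the
#' margin (log-odds) scale. Per instance, the Shapley contributions plus
#' the base value reproduce the model margin (local accuracy).
#'
#' @param object a `fatigue_boosting` fit.
#' @param features predictor tibble to explain.
#' @return A list of class `attribution_report`: `importance` (tibble of
#'   `feature`, `importance_pct` summing to 100), `shap` (tibble of
#'   per-instance contributions), `shap_base` (expected margin), `margin`
#'   (per-instance model margin).
#' @export
#' @examples
#' \donttest{
#' X <- tibble::tibble(a = rnorm(200), b = rnorm(200))
#' y <- as.integer(X$a > 0)
#' fit <- fit_boosting(X, y)
#' rep <- attributions(fit, X)
#' sum(rep$importance$importance_pct)
#' }
attributions <- function(object, features) {
  if (!inherits(object, "fatigue_boosting"))
    abort("attributions requires a fitted fatigue_boosting model.")
  if (length(object$feature_names) == 1) {
    # a one-feature ensemble trivially owns all of the gain
    imp <- tibble(feature = object$feature_names, importance_pct = 100)
  } else {
    imp_raw <- xgboost::xgb.importance(model = object$booster)
    imp <- tibble(feature = object$feature_names) %>%
      left_join(tibble(feature = imp_raw$Feature, gain = imp_raw$Gain),
                by = "feature") %>%
      mutate(gain = tidyr::replace_na(gain, 0),
             importance_pct = 100 * gain / sum(gain)) %>%
      select(feature, importance_pct) %>%
      arrange(dplyr::desc(importance_pct))
  }

  X <- prep_matrix(object, features)
  contrib <- predict(object$booster, xgboost::xgb.DMatrix(X),
                     predcontrib = TRUE)
  p <- ncol(contrib)
  shap <- as_tibble(as.data.frame(contrib[, -p, drop = FALSE]))
  base <- contrib[1, p]
  margin <- predict(object$booster, xgboost::xgb.DMatrix(X),
                    outputmargin = TRUE)
  structure(list(importance = imp, shap = shap, shap_base = base,
                 margin = margin),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("<attribution_report>\n top features (% gain):\n")
  top <- head(x$importance, 5)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-24s %5.1f%%\n", top$feature[i], top$importance_pct[i]))
  }
  invisible(x)
}
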