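#' Rank-statistic ROC AUC
#'
#' Tie-corrected Mann-Whitney form: `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)`
#' where `R1` is the rank-sum of the positive scores (average ranks for
#' ties). Equivalent to the proportion of positive/negative pairs ranked
#' correctly, counting ties as one half.
#'
#' @param y_true binary labels (0/1, logical, or a factor whose second level
#'   is the positive class).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`; `NA` when only one class is present.
#' @export
#' @examples
#' auc_rank(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.85))
auc_rank <- function(y_true, scores) {
  y <- as_binary_label(y_true)
  ok <- !is.na(y) & !is.na(scores)
  y <- y[ok]; scores <- scores[ok]
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_label <- function(y) {
  if (is.factor(y)) return(as.integer(y == levels(y)[2]))
  if (is.logical(y)) return(as.integer(y))
  if (!all(y %in% c(0, 1, NA))) abort("labels must be binary.")
  as.integer(y)
}

#' Single-split classification metrics
#'
#' Accuracy, sensitivity, specificity and F1 at a probability threshold,
#' plus the rank-statistic AUC.
#'
#' @param y_true binary labels.
#' @param scores predicted probabilities in `[0, 1]`.
#' @param threshold decision threshold for the class metrics (default 0.5).
#' @return A one-row tibble `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `auc`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  if (any(scores < 0 | scores > 1, na.rm = TRUE))
    abort("scores must lie in [0, 1].")
  y <- as_binary_label(y_true)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  f1 <- if (is.na(ppv) || is.na(sens) || ppv + sens == 0) 0 else
    2 * ppv * sens / (ppv + sens)
  tibble(
    accuracy = (tp + tn) / length(y),
    sensitivity = sens,
    specificity = spec,
    f1 = f1,
    auc = auc_rank(y, scores)
  )
}

#' ROC curve and Youden-optimal operating point
#'
#' Sweeps every observed score as a threshold (predict positive when
#' `score >= t`), returns the ROC points and the operating point maximising
#' the Youden index `J = sensitivity + specificity - 1`; ties are broken
#' toward higher specificity.
#'
#' @param y_true binary labels (both classes present).
#' @param scores numeric scores.
#' @return A list: `roc` (tibble of threshold/sensitivity/specificity),
#'   `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
roc_youden <- function(y_true, scores) {
  y <- as_binary_label(y_true)
  if (length(unique(y)) < 2) abort("both classes must be present.")
  thr <- sort(unique(scores), decreasing = TRUE)
  thr <- c(Inf, thr)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n0, numeric(1))
  roc <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]  # prefer the more specific point
  list(roc = roc, threshold = thr[best], sensitivity = sens[best],
       specificity = spec[best], youden = j[best])
}

#' Stratified-random dummy baseline
#'
#' The no-skill reference: each repetition predicts a positive label with
#' the empirical class probability, independently of the truth, and the
#' binary predictions are scored like any other model. Expected AUC is 0.5.
#'
#' @param y binary labels.
#' @param seed optional seed.
#' @param reps repetitions (default 100).
#' @param threshold decision threshold passed to [compute_metrics()].
#' @return A `fatigue_cv` object (see [run_cv()]) whose folds are the
#'   repetitions.
#' @export
#' @examples
#' panel <- dummy_baseline(rbinom(500, 1, 0.15), seed = 1, reps = 50)
#' glance(panel)$auc_mean
dummy_baseline <- function(y, seed = NULL, reps = 100, threshold = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  yb <- as_binary_label(y)
  if (length(unique(yb)) < 2) abort("labels have a single class.")
  p <- mean(yb)
  folds <- purrr::map_dfr(seq_len(reps), function(r) {
    scores <- as.numeric(runif(length(yb)) < p)
    compute_metrics(yb, scores, threshold) %>% mutate(fold = r, .before = 1)
  })
  new_fatigue_cv(folds, model = "dummy_stratified", scheme = "resample",
                 n = length(yb))
}
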