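#' ROC curve plot
#'
#' @param roc the list returned by [roc_youden()].
#' @return A ggplot object with the ROC curve and the Youden-optimal
#'   operating point.
#' @export
plot_roc <- function(roc) {
  df <- roc$roc %>% arrange(1 - specificity, sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - specificity, y = sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::annotate("point", x = 1 - roc$specificity, y = roc$sensitivity,
                      colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("Youden J = %.3f at threshold %.3f",
                                     roc$youden, roc$threshold)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Correlation heat map
#'
#' @param object a `cor_result` from [correlation_matrix()].
#' @param ... unused.
#' @return A ggplot heat map of the correlation matrix.
#' @export
autoplot.cor_result <- function(object, ...) {
  df <- as.data.frame(as.table(object$r))
  names(df) <- c("var1", "var2", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 2.7) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Feature-importance bar chart
#'
#' @param object an `attribution_report` from [attributions()].
#' @param top_n features to display.
#' @param ... unused.
#' @return A ggplot bar chart of percentage importances.
#' @export
autoplot.attribution_report <- function(object, top_n = 13, ...) {
  df <- head(object$importance, top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = importance_pct,
                                   y = stats::reorder(feature, importance_pct))) +
    ggplot2::geom_col(fill = "#4C72B0") +
    ggplot2::labs(x = "Importance (% gain)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Per-fold metric distribution of a cross-validation run
#'
#' @param object a `fatigue_cv` object.
#' @param ... unused.
#' @return A ggplot of the per-fold metric values.
#' @export
autoplot.fatigue_cv <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(c(accuracy, sensitivity, specificity, f1, auc),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = metric, y = value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = sprintf("%s / %s", object$model, object$scheme)) +
    ggplot2::theme_minimal()
}
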