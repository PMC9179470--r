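#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_tile
#'   geom_text labs theme_minimal scale_fill_gradient facet_wrap
#' @export
ggplot2::autoplot

#' Plot the optimizer convergence history
#'
#' @param object A `cssa_result`.
#' @param ... Unused.
#' @return A ggplot of incumbent-best and mean fitness per iteration.
#' @method autoplot cssa_result
#' @export
autoplot.cssa_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("f_g", "mean_fitness"),
                            names_to = "series", values_to = "fitness")
  ggplot(df, aes(x = .data$iteration, y = .data$fitness,
                 color = .data$series)) +
    geom_line() +
    labs(x = "Iteration", y = "Fitness (lower is better)", color = NULL,
         title = "Chaotic sparrow search convergence") +
    theme_minimal()
}

#' Plot training and validation accuracy per epoch
#'
#' @param object An `sgru_fit`.
#' @param ... Unused.
#' @return A ggplot of the accuracy history.
#' @method autoplot sgru_fit
#' @export
autoplot.sgru_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("train_accuracy", "val_accuracy"),
                            names_to = "series", values_to = "accuracy")
  df <- df[!is.na(df$accuracy), ]
  ggplot(df, aes(x = .data$epoch, y = .data$accuracy,
                 color = .data$series)) +
    geom_line() +
    labs(x = "Epoch", y = "Accuracy", color = NULL,
         title = "Stacked GRU training history") +
    theme_minimal()
}

#' Plot a per-class metrics report as grouped bars
#'
#' @param object A [metrics_report()] tibble.
#' @param ... Unused.
#' @return A ggplot faceted by metric.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object, c("accuracy", "precision", "recall", "specificity", "fscore",
              "mcc", "gmean"),
    names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$class, y = .data$value)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~metric) +
    labs(x = NULL, y = "Percent", title = "One-vs-rest metrics by class") +
    theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' @param cm A `confusion_matrix`.
#' @return A ggplot tile plot with counts.
#' @export
plot_confusion <- function(cm) {
  df <- as.data.frame(as.table(unclass(cm)))
  names(df) <- c("true", "predicted", "count")
  ggplot(df, aes(x = .data$predicted, y = .data$true,
                 fill = .data$count)) +
    geom_tile() +
    geom_text(aes(label = .data$count), size = 3) +
    scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = "Predicted class", y = "True class",
         title = "Confusion matrix") +
    theme_minimal()
}
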