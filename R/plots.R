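#' Heatmap of a similarity matrix
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy(object)
  df$id1 <- factor(df$id1, levels = rownames(object))
  df$id2 <- factor(df$id2, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id1, y = .data$id2,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(0, min(df$similarity)), NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity",
                  title = sprintf("%s kernel", attr(object, "method"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Per-fold AUC distributions of a cross-validation run
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("auc_roc", "auc_pr"),
                            names_to = "metric", values_to = "auc")
  df$metric <- factor(df$metric, levels = c("auc_roc", "auc_pr"),
                      labels = c("AUC-ROC", "AUC-PR"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(ggplot2::aes(colour = factor(.data$repeat_)),
                         width = 0.08, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "area under curve", colour = "repeat",
                  title = sprintf("%s: %d x %d-fold CV", object$method,
                                  object$n_repeats, object$n_folds)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
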