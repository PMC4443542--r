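#' Plot a ROC curve
#'
#' @param object A `domarch_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.domarch_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot benchmark AUCs per measure configuration
#'
#' @param object A `domarch_benchmark` from [benchmark_measures()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.domarch_benchmark <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$auc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(min(0.5, min(df$auc)), 1)) +
    ggplot2::labs(x = NULL, y = "AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of the unique-DA similarity table
#'
#' @param table A `domarch_datable` from [pairwise_da_similarities()].
#' @return A ggplot.
#' @export
plot_da_similarity <- function(table) {
  stopifnot(inherits(table, "domarch_datable"))
  n <- length(table$da_strings)
  df <- tibble::tibble(
    i = rep(seq_len(n), each = n),
    j = rep(seq_len(n), times = n),
    similarity = as.vector(t(table$sims))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "DA index", y = "DA index") +
    ggplot2::theme_minimal()
}

#' Sub-space size distribution of a partition
#'
#' @param p A `domarch_partition`.
#' @return A ggplot.
#' @export
plot_partition_sizes <- function(p) {
  stopifnot(inherits(p, "domarch_partition"))
  sizes <- tibble::tibble(size = as.integer(table(p$assignment)))
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "DAs per sub-space", y = "Sub-spaces") +
    ggplot2::theme_minimal()
}
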