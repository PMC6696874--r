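#' Plot a 2-D cell embedding
#'
#' Scatter plot of embedding coordinates, optionally colored by a per-cell
#' label (cluster or cell type).
#'
#' @param object An `embedding`.
#' @param labels Optional vector of per-cell labels in embedding row order,
#'   or a tibble with `cell_id` and a label column.
#' @param label_name Legend title when labels are given.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embedding <- function(object, labels = NULL, label_name = "label",
                               ...) {
  df <- tidy(object)
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      labels <- tibble::as_tibble(labels)
      lab_col <- setdiff(names(labels), "cell_id")[1]
      df <- dplyr::left_join(df, labels, by = "cell_id")
      names(df)[names(df) == lab_col] <- "label"
    } else {
      df$label <- as.factor(labels)
    }
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                          color = factor(.data$label))) +
      ggplot2::labs(color = label_name)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p + ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' Plot cluster annotation enrichment
#'
#' Tile plot of normalized enrichment scores per cluster and reference cell
#' type, with the assigned type outlined.
#'
#' @param object A `cluster_annotation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_annotation <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$cell_type, factor(.data$cluster),
                               fill = .data$nes)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(object$table, .data$assigned),
                       color = "black", linewidth = 0.8, fill = NA) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  midpoint = 0) +
    ggplot2::labs(x = "reference cell type", y = "cluster", fill = "NES") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-cell QC statistics
#'
#' Histograms of detected genes, total UMI and mitochondrial fraction with
#' pass/fail coloring.
#'
#' @param object A `qc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_result <- function(object, ...) {
  long <- object$report |>
    tidyr::pivot_longer(c("n_genes", "n_umi", "mito_fraction"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, fill = .data$pass)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "cells", fill = "pass") +
    ggplot2::theme_minimal()
}
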