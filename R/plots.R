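#' Bar chart of a per-amino-acid index summary
#'
#' Mean index value per amino acid with ±1 sd error bars — the standard
#' presentation of RSCU/MRCBS profiles across a corpus.
#'
#' @param summary_tbl A tibble from [amino_acid_summary()].
#' @param title Plot title.
#' @param ylab Y-axis label.
#' @return A ggplot object.
#' @export
plot_amino_acid_summary <- function(summary_tbl, title = NULL,
                                    ylab = "mean index value") {
  ggplot2::ggplot(
    summary_tbl,
    ggplot2::aes(
      x = stats::reorder(.data$amino_acid, -.data$mean),
      y = .data$mean
    )
  ) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = .data$mean + .data$sd),
      width = 0.3, colour = "red"
    ) +
    ggplot2::labs(x = NULL, y = ylab, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)
    )
}

#' Histogram of per-codon index values
#'
#' @param index_tbl A per-codon index tibble.
#' @param value_col Column to plot.
#' @param bins Number of bins.
#' @return A ggplot object.
#' @export
plot_index_distribution <- function(index_tbl, value_col = "rscu",
                                    bins = 30) {
  ggplot2::ggplot(index_tbl, ggplot2::aes(x = .data[[value_col]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::labs(x = value_col, y = "count") +
    ggplot2::theme_minimal()
}

#' Scree plot of a codon-usage PCA
#'
#' @param object A `codon_pca` from [pca_indices()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.codon_pca <- function(object, ...) {
  d <- tidy.codon_pca(object)
  ggplot2::ggplot(
    d, ggplot2::aes(x = .data$component, y = .data$eigenvalue)
  ) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.0f%%", 100 * .data$proportion)),
      vjust = -0.4
    ) +
    ggplot2::labs(x = NULL, y = "eigenvalue") +
    ggplot2::theme_minimal()
}
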