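#' Plot a stability result
#'
#' Bar chart of the per-gene stability metric, ordered from most to least
#' stable (lower bars = more stable).
#'
#' @param object An `rg_stability` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rg_stability <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = stats::reorder(.data$gene_id, .data$metric),
                                   y = .data$metric)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "stability metric (cycles)",
                  title = paste("Candidate stability:", object$algorithm)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a comprehensive ranking
#'
#' @param object An `rg_ranking`.
#' @param ... Unused.
#' @return A ggplot of the geometric-mean score per gene, best first.
#' @export
autoplot.rg_ranking <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = stats::reorder(.data$gene_id, .data$geomean),
                                   y = .data$geomean)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "geometric mean of ranks",
                  title = "Comprehensive reference-gene ranking") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot relative quantities
#'
#' @param object An `rq_table` from [relative_expression()].
#' @param ... Unused.
#' @return A ggplot: one bar per sample, milestone at 1 (dashed line).
#' @export
autoplot.rq_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_id, y = .data$rq,
                                       fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "relative quantity (fold vs milestone)",
                  title = sprintf("%s normalized to %s",
                                  attr(object, "target"),
                                  attr(object, "reference"))) +
    ggplot2::theme_minimal()
}

#' Plot a sample PCA
#'
#' @param object An `rg_pca` from [pca_samples()].
#' @param ... Unused.
#' @return A ggplot of the first two axes, points labelled by sample and
#'   coloured by condition, with variance fractions in the axis labels.
#' @export
autoplot.rg_pca <- function(object, ...) {
  co <- object$coordinates
  ve <- object$var_explained
  if (!"PC2" %in% names(co)) co$PC2 <- 0
  ggplot2::ggplot(co, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$condition,
                                   label = .data$sample_id)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = if (length(ve) > 1) sprintf("PC2 (%.1f%%)", 100 * ve[2]) else "PC2",
                  title = "Sample PCA (genes centred, unscaled)") +
    ggplot2::theme_minimal()
}
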