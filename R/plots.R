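#' Radar-style plot of per-mark occurrence weights
#'
#' Displays the [mark_weight_tally()] counts for upregulated and
#' downregulated genes on a polar axis, one spoke per mark.
#'
#' @param tally Output of [mark_weight_tally()].
#' @return A ggplot object.
#' @export
plot_mark_radar <- function(tally) {
  long <- tidyr::pivot_longer(tally, c("up", "down"),
                              names_to = "de_class", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mark, y = .data$n,
                                     group = .data$de_class,
                                     colour = .data$de_class,
                                     fill = .data$de_class)) +
    ggplot2::geom_polygon(alpha = 0.2) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "genes with mark", colour = "DE class",
                  fill = "DE class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}

#' Histogram of modification-type burden by DE class
#'
#' @param burden Output of [modification_burden()].
#' @param percentage Plot percentages per class instead of counts.
#' @return A ggplot object.
#' @export
plot_burden <- function(burden, percentage = FALSE) {
  h <- burden$histogram
  y <- if (percentage) "pct" else "n"
  ggplot2::ggplot(h, ggplot2::aes(x = factor(.data$burden),
                                  y = .data[[y]], fill = .data$de_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "epigenetic modification types per gene",
                  y = if (percentage) "% of genes" else "genes",
                  fill = "DE class") +
    ggplot2::theme_minimal()
}

#' Heatmap of the per-gene mark matrix
#'
#' Genes (rows, ordered by DE class then descending mark count)
#' against mark columns.
#'
#' @param mm Mark matrix from [build_mark_matrix()].
#' @return A ggplot object.
#' @export
plot_mark_heatmap <- function(mm) {
  marks <- intersect(mark_names, names(mm))
  ord <- order(mm$de_class, -rowSums(as.matrix(mm[, marks])))
  long <- tidyr::pivot_longer(
    dplyr::mutate(mm[ord, c("gene_id", marks)],
                  gene_id = factor(.data$gene_id, levels = rev(.data$gene_id))),
    -"gene_id", names_to = "mark", values_to = "present")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mark, y = .data$gene_id,
                                     fill = .data$present)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mark present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Clonal-group size spectrum
#'
#' @param clonal Output of [clonal_summary()].
#' @return A ggplot object.
#' @export
plot_clonal_spectrum <- function(clonal) {
  ggplot2::ggplot(clonal$spectrum,
                  ggplot2::aes(x = factor(.data$size),
                               y = .data$cell_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "clonal group size (cells)",
                  y = "fraction of cells") +
    ggplot2::theme_minimal()
}
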