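# ggplot2 renderings of the three summary types.

#' Plot per-taxon coverage percentages
#'
#' Horizontal bar chart of coverage per taxon; with several primer pairs in
#' `data` (a `pair` column), bars are dodged per pair.
#'
#' @param data A [coverage_by_taxon()] table, optionally with a `pair`
#'   column stacking several pairs.
#' @return A ggplot object.
#' @export
plot_coverage <- function(data) {
  data <- dplyr::mutate(
    data, taxon_label = factor(.data$taxon_label,
                               levels = rev(unique(.data$taxon_label)))
  )
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$percent,
                                          y = .data$taxon_label))
  if ("pair" %in% names(data)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$pair),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p +
    ggplot2::labs(x = "Sequences amplified (%)", y = NULL, fill = NULL) +
    ggplot2::xlim(0, 100) +
    ggplot2::theme_minimal()
}

#' @method autoplot coverage_table
#' @export
autoplot.coverage_table <- function(object, ...) plot_coverage(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot unidentified-taxon counts per rank
#'
#' @param data An [unidentified_counts()] table, optionally with a `pair`
#'   column stacking several pairs.
#' @return A ggplot object.
#' @export
plot_unidentified <- function(data) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$rank,
                                          y = .data$n_unidentified))
  if ("pair" %in% names(data)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$pair),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p +
    ggplot2::labs(x = "Taxonomic rank", y = "Unidentified records",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-phylum representation
#'
#' @param data A [phylum_representation()] table, optionally with a `pair`
#'   column.
#' @return A ggplot object.
#' @export
plot_phylum_representation <- function(data) {
  data <- dplyr::mutate(
    data, phylum = factor(.data$phylum, levels = rev(unique(.data$phylum)))
  )
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$n_amplified,
                                          y = .data$phylum))
  if ("pair" %in% names(data)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$pair),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p +
    ggplot2::labs(x = "Amplified records", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
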