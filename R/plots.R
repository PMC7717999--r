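#' Heatmap of GST relative abundance across samples
#'
#' @param abundance long tibble with `sample_id`, `gst_id`, `relative`
#'   (see [abundance_long()]).
#' @return a ggplot.
#' @export
plot_abundance_heatmap <- function(abundance) {
  ggplot2::ggplot(abundance,
                  ggplot2::aes(x = .data$sample_id,
                               y = factor(.data$gst_id),
                               fill = .data$relative)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "relative\nabundance", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "GST") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Principal-coordinates ordination plot
#'
#' @param d symmetric sample distance matrix.
#' @param groups optional named vector sample id -> group label for coloring.
#' @return a ggplot of the first two principal coordinates.
#' @export
plot_pcoa <- function(d, groups = NULL) {
  xy <- pcoa_coords(d, k = 2)
  ef <- attr(xy, "eig_fraction")
  if (!is.null(groups)) xy$group <- groups[xy$sample_id]
  p <- ggplot2::ggplot(xy, ggplot2::aes(x = .data$PCo1, y = .data$PCo2)) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", 100 * ef[1]),
                  y = sprintf("PCo2 (%.1f%%)", 100 * ef[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point(size = 2)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
}

#' Gene-profiling accuracy by coverage
#'
#' @param bench output of [gene_profile_benchmark()].
#' @return a ggplot of per-genome TPR and F1 versus coverage.
#' @export
plot_profile_accuracy <- function(bench) {
  long <- tidyr::pivot_longer(bench, c("tpr", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$coverage), y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~ .data$metric) +
    ggplot2::labs(x = "fold coverage", y = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for abundance profiles
#'
#' @param object an `abundance_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot abundance_profile
#' @export
autoplot.abundance_profile <- function(object, ...) {
  df <- mutate(as_tibble(object),
               sample_id = attr(object, "sample_id") %||% "sample")
  plot_abundance_heatmap(df)
}
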