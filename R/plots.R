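#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a saturation curve
#'
#' nRF distance to the reference and mean bootstrap support against the
#' number of concatenated genes.
#'
#' @param object A `saturation_curve`.
#' @param ... Unused.
#' @method autoplot saturation_curve
#' @export
autoplot.saturation_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("nrf_to_reference", "mean_support"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_genes, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "genes concatenated", y = NULL,
                  title = sprintf("Saturation (%s ordering)",
                                  attr(object, "ordering"))) +
    ggplot2::theme_minimal()
}

#' Plot a completeness matrix as a heatmap
#'
#' @param object A `completeness` object.
#' @param ... Unused.
#' @method autoplot completeness
#' @export
autoplot.completeness <- function(object, ...) {
  ggplot2::ggplot(object$long,
                  ggplot2::aes(x = .data$gene_id, y = .data$sample_id,
                               fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "gene", y = "sample",
                  fill = "fraction of\nreference length") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot topology clusters in the 2D MDS embedding
#'
#' @param report Result of [topology_clusters()].
#' @return A ggplot object.
#' @export
plot_topology_clusters <- function(report) {
  df <- report$coordinates
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$cluster)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(title = sprintf("%d topology cluster(s)",
                                  report$n_clusters),
                  x = "MDS 1", y = "MDS 2") +
    ggplot2::theme_minimal()
}

#' Plot intra- vs interspecific distances across loci counts
#'
#' @param object A `loci_resampling` tibble.
#' @param ... Unused.
#' @method autoplot loci_resampling
#' @export
autoplot.loci_resampling <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$n_loci),
                               y = .data$distance, fill = .data$type)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pair)) +
    ggplot2::labs(x = "loci sampled", y = "concatenated distance",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-bait QC annotations
#'
#' GC against repeat content, colored by pass/fail.
#'
#' @param baits The `baits` tibble from [design_bait_set()].
#' @return A ggplot object.
#' @export
plot_bait_qc <- function(baits) {
  ggplot2::ggplot(baits, ggplot2::aes(x = .data$gc_pct, y = .data$repeat_pct,
                                      color = .data$passed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "GC (%)", y = "repeat (%)", color = "passed") +
    ggplot2::theme_minimal()
}
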