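#' Plot per-gene SNP count and density distributions
#'
#' Histograms of the number of SNPs per gene and of SNPs per 100 bp of
#' exonic length, for genes carrying at least one SNP.
#'
#' @param gene_stats Output of [snp_gene_stats()].
#' @return A ggplot object (two facets: count and per-100bp density).
#' @export
plot_snp_gene_stats <- function(gene_stats) {
  df <- gene_stats |>
    filter(.data$snp_count > 0) |>
    tidyr::pivot_longer(c("snp_count", "snps_per_100bp"),
                        names_to = "metric", values_to = "value") |>
    mutate(metric = dplyr::recode(.data$metric,
                                  snp_count = "SNPs per gene",
                                  snps_per_100bp = "SNPs per 100 bp"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey30") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "Genes") +
    ggplot2::theme_minimal()
}

#' Plot the core/dispensable transcriptome histogram
#'
#' @param histogram Output of [core_dispensable_histogram()].
#' @return A ggplot bar chart of gene counts by number of expressing
#'   lines.
#' @export
plot_core_dispensable <- function(histogram) {
  n_lines <- attr(histogram, "n_lines")
  df <- histogram |>
    mutate(part = dplyr::case_when(
      .data$n_lines_expressed == n_lines ~ "core",
      .data$n_lines_expressed == 0 ~ "never expressed",
      TRUE ~ "dispensable"
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_lines_expressed,
                                   y = .data$n_genes, fill = .data$part)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Lines in which gene is expressed", y = "Genes",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a novelty-filter cutoff sweep
#'
#' @param sweep Output of [cutoff_sweep()].
#' @return A ggplot line chart: removed transcripts vs. coverage cutoff,
#'   one line per identity cutoff.
#' @export
plot_cutoff_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$cov_cut, y = .data$n_removed,
                                      colour = factor(.data$id_cut))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Coverage cutoff", y = "Transcripts removed",
                  colour = "Identity cutoff") +
    ggplot2::theme_minimal()
}

#' Plot transcript presence/absence frequency across lines
#'
#' @param classification Output of [classify_support()].
#' @return A ggplot bar chart of transcripts by number of supporting
#'   lines.
#' @export
plot_pav_frequency <- function(classification) {
  ggplot2::ggplot(classification,
                  ggplot2::aes(x = .data$n_lines_supported,
                               fill = .data$category)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "Lines with read support", y = "Transcripts",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a Rogers distance matrix
#'
#' @param object A `rogers_dist` object.
#' @param ... Unused.
#' @return A ggplot tile heatmap.
#' @exportS3Method ggplot2::autoplot
autoplot.rogers_dist <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$line_1, y = .data$line_2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Rogers d") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
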