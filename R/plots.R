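#' Heatmap of pairwise residual correlations within a compartment
#'
#' @param report An `inflaclust_report`.
#' @param compartment `"blood"` or `"csf"`.
#' @return A ggplot.
#' @export
plot_cluster_correlations <- function(report,
                                      compartment = c("blood", "csf")) {
  compartment <- match.arg(compartment)
  d <- report$cluster_correlations
  d <- d[d$compartment == compartment, , drop = FALSE]
  d2 <- d
  names(d2)[1:2] <- c("analyte_2", "analyte_1")
  d <- dplyr::bind_rows(d, d2)
  ggplot2::ggplot(d, ggplot2::aes(.data$analyte_1, .data$analyte_2,
                                  fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = paste("Residual correlations,", compartment)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Cluster scores by diagnosis group
#'
#' Box-and-jitter panels of per-patient cluster scores split by diagnosis
#' group, one facet per cluster.
#'
#' @param report An `inflaclust_report`.
#' @return A ggplot.
#' @export
plot_cluster_scores <- function(report) {
  clusters <- report$cluster_definitions$cluster
  long <- tidyr::pivot_longer(
    report$scores[, c("subject_id", "diagnosis", clusters)],
    dplyr::all_of(clusters), names_to = "cluster", values_to = "score")
  ggplot2::ggplot(long[!is.na(long$score), ],
                  ggplot2::aes(.data$diagnosis, .data$score,
                               colour = .data$diagnosis)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Cluster score (adjusted Z residual)") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Grid of cluster-severity Spearman correlations
#'
#' Tile plot of the Spearman rho between each cluster score and each MS
#' severity scale, faceted by sub-cohort; significant cells (adjusted
#' p < 0.05) are outlined.
#'
#' @param report An `inflaclust_report`.
#' @return A ggplot.
#' @export
plot_severity_grid <- function(report) {
  d <- report$severity
  d$sig <- !is.na(d$p_adjusted) & d$p_adjusted < 0.05
  ggplot2::ggplot(d, ggplot2::aes(.data$variable_2, .data$variable_1,
                                  fill = .data$estimate)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_tile(data = d[d$sig, , drop = FALSE], fill = NA,
                       colour = "black", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$estimate)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::labs(x = "Severity scale", y = "Cluster",
                  fill = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' @rdname run_pipeline
#' @param object An `inflaclust_report`.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.inflaclust_report <- function(object, ...) {
  plot_cluster_scores(object)
}
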