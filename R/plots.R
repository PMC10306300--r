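# Plotting helpers for the main result types.

#' Plot IFN score distributions by group
#'
#' Jittered per-sample IFN scores with median/IQR boxes, split by a
#' metadata grouping (karyotype by default).
#'
#' @param scores Scores tibble (`sample_id`, `ifn_score`).
#' @param metadata Cohort metadata.
#' @param group Metadata column used for grouping.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, metadata, group = "karyotype") {
  meta <- metadata[match(scores$sample_id, metadata$sample_id), ]
  df <- dplyr::mutate(scores, group = meta[[group]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$ifn_score)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = group, y = "IFN score") +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of an association screen
#'
#' @param assoc Association tibble (`feature`, `estimate`, `p`, `q`).
#' @param q_max Significance threshold used for colouring.
#' @return A ggplot object.
#' @export
plot_association <- function(assoc, q_max = 0.1) {
  df <- dplyr::mutate(assoc,
                      significant = !is.na(.data$q) & .data$q < q_max)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = unique(assoc$kind)[1], y = "-log10 p",
                  colour = sprintf("q < %.2g", q_max)) +
    ggplot2::theme_minimal()
}

#' Observed/expected heatmap of condition enrichment
#'
#' @param enrichment A [condition_enrichment()] result.
#' @return A ggplot object.
#' @export
plot_condition_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment$oe,
                  ggplot2::aes(x = factor(.data$cluster), y = .data$condition,
                               fill = log2(.data$oe_ratio))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "cluster", y = NULL, fill = "log2 O/E") +
    ggplot2::theme_minimal()
}
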