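#' Plot Kaplan-Meier curves
#'
#' @param object An `lnc_km` step table from [kaplan_meier()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lnc_km <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(object, .data$n_censor > 0),
                        shape = 3, size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = "Expression") +
    ggplot2::theme_minimal()
}

#' Plot a GSEA running sum
#'
#' @param object An `lnc_gsea` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lnc_gsea <- function(object, ...) {
  rs <- object$running_sum
  subtitle <- sprintf("ES = %.3f", object$es)
  if (!is.null(object$p_perm)) {
    subtitle <- sprintf("%s, p_perm = %.3g (%d permutations)",
                        subtitle, object$p_perm, object$n_perm)
  }
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_rug(data = dplyr::filter(rs, .data$hit), sides = "b") +
    ggplot2::labs(title = object$set_name, subtitle = subtitle,
                  x = "Rank in ordered list", y = "Running enrichment score") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a per-dataset differential expression result
#'
#' @param de A [dataset_de()] tibble.
#' @param alpha Significance threshold drawn on the plot.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, alpha = 0.01) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_adj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (tumor - normal)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Heatmap of signature features across samples
#'
#' Rows and columns are ordered by hierarchical clustering (correlation
#' distance, average linkage); values are row-standardized.
#'
#' @param mat Feature x sample matrix (e.g. a top-signature submatrix).
#' @param labels Optional per-sample labels drawn as a column strip.
#' @return A ggplot object.
#' @export
plot_signature_heatmap <- function(mat, labels = NULL) {
  z <- t(scale(t(mat)))
  row_ord <- hierarchical_cluster(z)$order
  col_ord <- hierarchical_cluster(t(z))$order
  df <- as_tibble(z[row_ord, col_ord, drop = FALSE], rownames = "feature") %>%
    tidyr::pivot_longer(-"feature", names_to = "sample",
                        values_to = "z") %>%
    mutate(feature = factor(.data$feature, levels = rownames(z)[row_ord]),
           sample = factor(.data$sample, levels = colnames(z)[col_ord]))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$feature,
                                        fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank())
  p
}
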