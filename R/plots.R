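# ggplot2 views of the main result types.

#' Volcano plot of a SAM result
#'
#' Mean difference (z-score units) against -log10 p, with the q-value
#' significance boundary implied by the attained |d| cutoff and s0.
#'
#' @param sam_rows A `sam_result` from [sam()].
#' @param boundary Draw the significance boundary curve (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_volcano <- function(sam_rows, boundary = TRUE) {
  p <- ggplot2::ggplot(sam_rows,
                       ggplot2::aes(x = .data$mean_diff, y = -log10(.data$p),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean difference (case - control, z units)",
                  y = expression(-log[10] ~ p), colour = "q < threshold") +
    ggplot2::theme_minimal()
  if (boundary && is.finite(attr(sam_rows, "d_cut"))) {
    b <- volcano_boundary(sam_rows)
    b <- b[is.finite(b$neg_log10_p), ]
    p <- p + ggplot2::geom_line(data = b, inherit.aes = FALSE,
                                ggplot2::aes(x = .data$mean_diff,
                                             y = .data$neg_log10_p),
                                linetype = "dashed", colour = "black")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.sam_result <- function(object, ...) plot_volcano(object, ...)

#' Mean/SD plot of a bootstrap-AUC result
#'
#' Bootstrap mean AUC against bootstrap SD per protein, the analogue of the
#' volcano plot for the resampling statistic.
#'
#' @param rows A `bootauc_result`, optionally after [bootauc_q()].
#' @return A ggplot object.
#' @export
plot_auc <- function(rows) {
  aes_col <- if (!is.null(rows$significant)) {
    ggplot2::aes(x = .data$mean_auc, y = .data$sd_auc, colour = .data$significant)
  } else {
    ggplot2::aes(x = .data$mean_auc, y = .data$sd_auc)
  }
  p <- ggplot2::ggplot(rows, aes_col) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "bootstrap mean AUC", y = "bootstrap SD of AUC") +
    ggplot2::theme_minimal()
  if (!is.null(rows$significant)) {
    p <- p + ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                                     `TRUE` = "firebrick"))
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.bootauc_result <- function(object, ...) plot_auc(object, ...)

#' PCA batch-diagnostic plot
#'
#' Samples on the first two principal components, coloured by batch and
#' shaped by group, with the mean batch silhouette in the subtitle.
#'
#' @param object A `tmt_pca` from [batch_pca()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tmt_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = factor(.data$batch),
                               shape = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(colour = "batch", shape = "group",
                  x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
                  subtitle = sprintf("mean batch silhouette = %.3f",
                                     object$silhouette)) +
    ggplot2::theme_minimal()
}

#' Enrichment bar plot
#'
#' Terms ordered by p-value with -log10 p bars, annotated with count/PH.
#'
#' @param rows Output of [ora()].
#' @param top Number of terms shown (default 15).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(rows, top = 15) {
  rows <- head(rows, top)
  rows$term <- factor(rows$term, levels = rev(rows$term))
  ggplot2::ggplot(rows, ggplot2::aes(x = -log10(.data$p), y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$count, .data$ph)),
                       hjust = -0.1, size = 3) +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL) +
    ggplot2::theme_minimal()
}
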