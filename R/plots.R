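## Figure helpers: PCA score scatter with group confidence ellipses, the
## amplitude (distance-to-reference) box plot, and one-vs-rest ROC curves.
## All return ggplot objects; callers decide device and size.

#' PCA score scatter by clinical group
#'
#' @param pca a [run_pca()] result.
#' @param metadata metadata for the scored samples.
#' @param components which two components to plot.
#' @param ellipses draw 95% confidence ellipses per group (groups with >= 3
#'   samples and non-degenerate covariance only).
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(pca, metadata, components = c(1, 2),
                            ellipses = TRUE) {
  sc <- pca$scores[, components, drop = FALSE]
  df <- data.frame(pc_a = sc[, 1], pc_b = sc[, 2],
                   group = group_labels(
                     metadata[match(rownames(sc), metadata$sample_id), ]))
  vf <- round(100 * pca$variance_fraction[components], 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$pc_a, .data$pc_b,
                                        colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("PC%d (%.1f%%)", components[1], vf[1]),
                  y = sprintf("PC%d (%.1f%%)", components[2], vf[2]),
                  colour = "group") +
    ggplot2::theme_bw()
  if (ellipses) {
    for (g in unique(df$group)) {
      m <- as.matrix(df[df$group == g, c("pc_a", "pc_b")])
      if (nrow(m) < 3) next
      ell <- tryCatch(confidence_ellipse(m), error = function(e) NULL)
      if (is.null(ell)) next
      th <- seq(0, 2 * pi, length.out = 120)
      rot <- matrix(c(cos(ell$rotation), sin(ell$rotation),
                      -sin(ell$rotation), cos(ell$rotation)), 2)
      pts <- t(rot %*% rbind(ell$semi_axes[1] * cos(th),
                             ell$semi_axes[2] * sin(th)) + ell$center)
      p <- p + ggplot2::geom_path(
        data = data.frame(pc_a = pts[, 1], pc_b = pts[, 2], group = g),
        linetype = 2)
    }
  }
  p
}

#' Amplitude box plot by group
#'
#' @param scores an [distance_to_reference()] result.
#' @return A ggplot object.
#' @export
plot_amplitude <- function(scores) {
  df <- scores$samples
  df$group <- factor(df$group,
                     levels = intersect(c("uninfected", "not_severe",
                                          "severe"), unique(df$group)))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$distance)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL,
                  y = sprintf("distance to %s centroid (first %d PCs)",
                              scores$reference_group, scores$n_components)) +
    ggplot2::theme_bw()
}

#' One-vs-rest ROC curves for a panel evaluation
#'
#' @param evaluation an [evaluate_severity_panel()] result.
#' @return A ggplot object.
#' @export
plot_roc <- function(evaluation) {
  dfs <- lapply(evaluation$evaluations, function(e) {
    if (!isTRUE(e$evaluable)) return(NULL)
    data.frame(fpr = e$roc$fpr, tpr = e$roc$tpr,
               curve = sprintf("%s (%s, AUC %.2f)", e$target, e$kind, e$auc))
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$curve)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 .data
NULL
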