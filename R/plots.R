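## Figure-style plots: quantile curves colored by genotype, per-centile
## delta curves with per-experiment traces and a loess fit, p-value vs
## centile with the 0.05 reference line, and the PCA bi-plot with
## loading arrows.

#' Plot quantile curves
#'
#' One line per experiment/condition; `truncate_at` restricts the view
#' to the lower quantiles (e.g. 0.8 to show "up to the 80th quantile").
#'
#' @param curves `"quantile_curve"` rows (e.g. `$curves` from
#'   [median_area_test()]).
#' @param truncate_at optional upper probability cutoff.
#' @return a ggplot object.
#' @export
plot_quantile_curves <- function(curves, truncate_at = NULL) {
  if (!is.null(truncate_at)) curves <- curves[curves$probs <= truncate_at, ]
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$probs, y = .data$values,
                                       group = .data$group,
                                       colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "quantile", y = "value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a centile-difference curve
#'
#' Per-experiment traces (dotted) with the loess fit (solid line).
#' @param cd a [centile_difference()] result.
#' @return a ggplot object.
#' @export
plot_centile_difference <- function(cd) {
  long <- data.frame(
    centile = rep(cd$centiles, each = cd$n_experiments),
    delta = as.vector(cd$per_experiment_delta),
    experiment = rep(rownames(cd$per_experiment_delta), length(cd$centiles)))
  fit <- data.frame(centile = cd$centiles, delta = cd$smooth_fit)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$centile, y = .data$delta)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$experiment),
                       linetype = "dotted", alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_line(data = fit, colour = "blue", linewidth = 1) +
    ggplot2::labs(x = "centile", y = "mutant - control quantile delta") +
    ggplot2::theme_minimal()
}

#' Plot per-centile p-values
#'
#' @param cd a [centile_difference()] result.
#' @param alpha reference significance line (default 0.05, drawn in red).
#' @return a ggplot object.
#' @export
plot_centile_pvalues <- function(cd, alpha = 0.05) {
  df <- data.frame(centile = cd$centiles, p = cd$p_value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centile, y = .data$p)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = alpha, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "centile", y = "p-value") +
    ggplot2::theme_minimal()
}

#' Plot a PCA bi-plot
#'
#' Samples as genotype-colored points; the `top_arrows` features with the
#' largest PC1/PC2 loading norms drawn as labelled arrows.
#'
#' @param pb a [pca_biplot()] result.
#' @param top_arrows number of loading arrows (default 5).
#' @return a ggplot object.
#' @export
plot_pca_biplot <- function(pb, top_arrows = 5) {
  sc <- data.frame(PC1 = pb$scores[, 1], PC2 = pb$scores[, 2],
                   genotype = pb$genotype)
  l <- pb$loadings[, 1:2, drop = FALSE]
  norm <- sqrt(rowSums(l^2))
  top <- order(-norm)[seq_len(min(top_arrows, nrow(l)))]
  mult <- 0.8 * max(abs(sc[, 1:2])) / max(norm[top])
  ar <- data.frame(feature = rownames(l)[top],
                   x = l[top, 1] * mult, y = l[top, 2] * mult)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$genotype), size = 3) +
    ggplot2::geom_segment(data = ar,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          arrow = grid::arrow(length = grid::unit(2, "mm")),
                          colour = "grey30") +
    ggplot2::geom_text(data = ar,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$feature),
                       vjust = -0.5, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * pb$variance_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * pb$variance_explained[2])) +
    ggplot2::theme_minimal()
}
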