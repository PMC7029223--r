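#' Plot the scoring matrix of a fitted clustering
#'
#' Heatmap of the scoring matrix with rows and columns ordered by cluster, so
#' the positive within-cluster / negative between-cluster block structure is
#' visible. Weakly assigned nodes are marked on the axis.
#'
#' @param object a `signed_clusters` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot signed_clusters
#' @export
autoplot.signed_clusters <- function(object, ...) {
  ord <- object$membership[order(object$membership$cluster,
                                 object$membership$node), ]
  m <- object$scoring$values[ord$node, ord$node]
  df <- tidyr::expand_grid(row = factor(ord$node, levels = ord$node),
                           col = factor(ord$node, levels = ord$node))
  df$score <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey85",
                                  high = "white", limits = c(-1, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = NULL, y = NULL, fill = "score",
                  title = sprintf("Scoring matrix (k = %d, sparsity %.2f)",
                                  object$k, object$sparsity)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the sparsity profile over the searched cluster numbers
#'
#' @param fit a `signed_clusters` or `cluster_assignment` object.
#' @return a ggplot of sparsity against k, the chosen k highlighted.
#' @export
plot_sparsity_profile <- function(fit) {
  stopifnot(!is.null(fit$profile))
  ggplot2::ggplot(fit$profile, ggplot2::aes(x = .data$k,
                                            y = .data$sparsity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = fit$profile[fit$profile$k == fit$k, ],
                        color = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = fit$profile$k) +
    ggplot2::labs(x = "number of clusters", y = "sparsity score") +
    ggplot2::theme_minimal()
}

#' Plot robustness confidence intervals
#'
#' Point ranges of the Jaccard-similarity percentile intervals, cluster-wise
#' and node-wise.
#'
#' @param object a `robustness_report`.
#' @param level `"cluster"`, `"node"` or `"both"` (default).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot robustness_report
#' @export
autoplot.robustness_report <- function(object, level = c("both", "cluster",
                                                         "node"), ...) {
  level <- match.arg(level)
  df <- tidy(object)
  if (level != "both") df <- df[df$level == level, ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$id,
                                                      .data$jaccard_mean),
                                   y = .data$jaccard_mean,
                                   ymin = .data$jaccard_lower,
                                   ymax = .data$jaccard_upper)) +
    ggplot2::geom_pointrange(size = 0.3) +
    ggplot2::facet_wrap(~ .data$level, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Jaccard similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
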