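#' Bar chart of movement-direction percentages
#'
#' @param summary Output of [summarize_directions()].
#' @return A ggplot object.
#' @export
plot_direction_summary <- function(summary) {
  assert_columns(summary, c("direction", "n", "percent"), "summary")
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = stats::reorder(.data$direction, -.data$n),
                               y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%% (n=%d)",
                                                    .data$percent,
                                                    as.integer(.data$n))),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of mobile transcripts",
                  title = "Movement direction of mobile mRNAs") +
    ggplot2::theme_minimal()
}

#' Rank plot of the delta2 - delta1 statistic with call thresholds
#'
#' @param deltas DEG or DIM table from [call_degs()] / [call_dims()].
#' @param threshold Cutoff drawn as horizontal lines.
#' @return A ggplot object.
#' @export
plot_delta_calls <- function(deltas, threshold = 2) {
  assert_columns(deltas, c("statistic", "call"), "deltas")
  df <- dplyr::arrange(deltas, .data$statistic) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$statistic,
                                   colour = .data$call)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "navy",
                                            none = "grey70")) +
    ggplot2::labs(x = "feature rank",
                  y = expression(Delta[2] - Delta[1] ~ "(log2)"),
                  title = "Heterograft difference-of-differences calls") +
    ggplot2::theme_minimal()
}

#' Score plot for a PCA summary
#'
#' @param object A `graft_pca` from [pca_summary()].
#' @param ... Unused.
#' @return A ggplot object of the first two component scores, axes labelled
#'   with explained-variance percentages.
#' @method autoplot graft_pca
#' @export
autoplot.graft_pca <- function(object, ...) {
  sc <- object$scores
  pcs <- setdiff(names(sc), "sample")[1:2]
  pct <- 100 * object$var_explained[1:2]
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample), vjust = -0.6,
                       size = 2.5) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", pcs[1], pct[1]),
                  y = sprintf("%s (%.1f%%)", pcs[2], pct[2]),
                  title = "PCA scores") +
    ggplot2::theme_minimal()
}

#' Fold-change heat map ordered by cluster
#'
#' @param object A `graft_clusters` from [cluster_metabolites()].
#' @param ... Unused.
#' @return A ggplot tile plot of the clustered profiles.
#' @method autoplot graft_clusters
#' @export
autoplot.graft_clusters <- function(object, ...) {
  ord <- object$assignments |>
    dplyr::arrange(.data$cluster) |>
    dplyr::mutate(row = dplyr::row_number())
  long <- as_tibble(object$data, rownames = "metabolite") |>
    tidyr::pivot_longer(-"metabolite", names_to = "contrast",
                        values_to = "log2fc") |>
    dplyr::inner_join(ord, by = "metabolite")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$contrast, y = .data$row,
                                     fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = "metabolites (cluster-ordered)",
                  title = sprintf("%d metabolite clusters", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1),
                   axis.text.y = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
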