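# ggplot2 methods for the result objects.

#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tidy(object)
  score_cols <- setdiff(names(df), c("unit_id", "cluster"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[score_cols[1]]],
    y = .data[[score_cols[min(2, length(score_cols))]]],
    colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(colour = "group",
                  title = sprintf("Regional typology (k = %d)",
                                  object$chosen_k)) +
    ggplot2::theme_minimal()
}

#' Elbow and silhouette curves for the k selection
#'
#' One panel per diagnostic: within-cluster sum of squares (the elbow
#' curve) and mean silhouette width, across the candidate k range. The
#' silhouette-maximizing k drives the grouping; the elbow is shown for the
#' human reader.
#'
#' @param x A [select_k_and_cluster()] result.
#' @return A ggplot object.
#' @export
plot_k_diagnostics <- function(x) {
  stopifnot(inherits(x, "cluster_result"))
  long <- tidyr::pivot_longer(x$diagnostics, -"k",
                              names_to = "diagnostic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = x$chosen_k, linetype = "dashed") +
    ggplot2::facet_wrap(~diagnostic, scales = "free_y") +
    ggplot2::labs(title = sprintf("k selection (chosen k = %d)", x$chosen_k)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.econet_pca <- function(object, ...) {
  ggplot2::ggplot(glance(object),
                  ggplot2::aes(x = .data$component, y = .data$ratio)) +
    ggplot2::geom_col() +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative, group = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::labs(y = "explained variance ratio",
                  title = "Principal components of the analysis variables") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tfp_models <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term %in% object$focal & td$model == td$term, ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$model, y = .data$estimate)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$estimate - 1.96 * .data$std.error,
      ymax = .data$estimate + 1.96 * .data$std.error), width = 0.15) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "coefficient on TFP change",
                  title = "Network position and TFP change") +
    ggplot2::theme_minimal()
}

#' Plot a directed economic network
#'
#' Draws the thresholded network with nodes at their panel coordinates when
#' supplied, otherwise on a deterministic force-directed layout.
#'
#' @param net An `econet_network`.
#' @param panel Optional panel supplying `x_coord`/`y_coord` per unit.
#' @param seed Layout seed when no coordinates are given.
#' @return A ggplot object.
#' @export
plot_network <- function(net, panel = NULL, seed = 1L) {
  stopifnot(inherits(net, "econet_network"))
  if (!is.null(panel)) {
    coords <- dplyr::distinct(panel[, c("unit_id", "x_coord", "y_coord")])
    coords <- coords[match(net$labels, coords$unit_id), ]
    xy <- cbind(coords$x_coord, coords$y_coord)
  } else {
    g <- igraph::graph_from_adjacency_matrix(net$adjacency,
                                             mode = "directed")
    xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  }
  idx <- which(net$adjacency == 1L, arr.ind = TRUE)
  edges <- tibble(x = xy[idx[, 1], 1], y = xy[idx[, 1], 2],
                  xend = xy[idx[, 2], 1], yend = xy[idx[, 2], 2])
  nodes <- tibble(unit_id = net$labels, x = xy[, 1], y = xy[, 2],
                  indegree = as.integer(colSums(net$adjacency)))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          alpha = 0.25,
                          arrow = ggplot2::arrow(length = ggplot2::unit(4, "pt"))) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$indegree)) +
    ggplot2::labs(title = sprintf("Economic network, density %.3f",
                                  net$density), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
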