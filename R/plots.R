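#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout with vertices sized by mean relative
#' abundance and edges coloured by sign.
#'
#' @param object A [cooc_network()].
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cooc_network <- function(object, seed = 1, ...) {
  de <- distinct_edges(object)
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  pos <- tibble(esv_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  ed <- de |>
    dplyr::left_join(pos, by = c(esv_a = "esv_id")) |>
    dplyr::left_join(pos, by = c(esv_b = "esv_id"),
                     suffix = c("", "_end")) |>
    dplyr::mutate(edge_sign = ifelse(.data$sign > 0, "positive", "negative"))
  v <- dplyr::left_join(pos, object$vertices, by = "esv_id")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_end, yend = .data$y_end,
                   colour = .data$edge_sign),
      alpha = 0.5, linewidth = 0.3) +
    ggplot2::geom_point(
      data = v,
      ggplot2::aes(x = .data$x, y = .data$y,
                   size = .data$mean_rel_abundance)) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#2166ac", negative = "#b2182b")) +
    ggplot2::scale_size_continuous(range = c(0.5, 4)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "edge sign", size = "mean rel. abundance")
}

#' Plot the degree distribution of a network on log-log axes
#'
#' @param net A [cooc_network()].
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(net) {
  g <- as_igraph(net)
  k <- igraph::degree(g)
  df <- dplyr::count(tibble(degree = k[k > 0]), .data$degree,
                     name = "frequency")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$frequency)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "degree k", y = "frequency")
}

#' Plot edge-class proportions per subnetwork
#'
#' @param classification An [classify_edges()] result.
#' @return A stacked-bar ggplot of generalist / specialist edge fractions.
#' @export
plot_edge_classes <- function(classification) {
  ggplot2::ggplot(classification$proportions,
                  ggplot2::aes(x = .data$environment,
                               y = .data$proportion,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "proportion of edges", fill = NULL)
}

#' Plot per-subnetwork negative-edge percentages
#'
#' @param profile A [negative_edge_profile()] result.
#' @return A bar ggplot.
#' @export
plot_negative_edges <- function(profile) {
  ggplot2::ggplot(profile$summary,
                  ggplot2::aes(x = stats::reorder(.data$environment,
                                                  .data$pct_negative),
                               y = .data$pct_negative)) +
    ggplot2::geom_col(fill = "#b2182b") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "% negative edges")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
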