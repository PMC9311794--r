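# ggplot2 views of the result objects. Layout is a simple family-grouped
# circle; these helpers are for quick inspection, not publication figures
# (the field lays its networks out in Gephi).

#' @rdname build_graph
#' @exportS3Method ggplot2::autoplot
autoplot.physio_graph <- function(object, ...) {
  nodes <- object$nodes
  ord <- order(nodes$family %|empty|% "", nodes$variable)
  nodes <- nodes[ord, ]
  k <- nrow(nodes)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  layout <- tibble(variable = nodes$variable, family = nodes$family,
                   x = cos(theta), y = sin(theta))
  edges <- object$edges
  seg <- dplyr::left_join(edges, layout[c("variable", "x", "y")],
                          by = c(from = "variable"))
  seg <- dplyr::left_join(seg, layout[c("variable", "x", "y")],
                          by = c(to = "variable"), suffix = c("", "_to"))
  p <- ggplot2::ggplot()
  if (nrow(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_to, yend = .data$y_to,
                   linewidth = .data$weight,
                   colour = .data$signed_r > 0),
      alpha = 0.5, show.legend = c(linewidth = FALSE, colour = TRUE)) +
      ggplot2::scale_linewidth(range = c(0.2, 1.2)) +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                              `FALSE` = "#b2182b"),
                                   labels = c(`TRUE` = "r > 0",
                                              `FALSE` = "r < 0"),
                                   name = NULL)
  }
  p +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$family), size = 2) +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(x = 1.08 * .data$x, y = 1.08 * .data$y,
                                    label = .data$variable), size = 2.2) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

`%|empty|%` <- function(x, y) ifelse(is.na(x), y, x)

#' @rdname centrality_report
#' @exportS3Method ggplot2::autoplot
autoplot.centrality_report <- function(object, ...) {
  df <- object$top5
  df$node <- factor(df$node, levels = rev(df$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$raw_value, y = .data$node,
                                   fill = factor(.data$rank))) +
    ggplot2::geom_col() +
    ggplot2::labs(title = sprintf("%s — %s", object$scenario, object$metric),
                  x = object$metric, y = NULL, fill = "rank") +
    ggplot2::theme_minimal()
}

#' Plot the tie-aware top-5 tables of several reports side by side
#'
#' @param reports List of `centrality_report` objects.
#' @return A ggplot.
#' @export
plot_top5 <- function(reports) {
  df <- dplyr::bind_rows(lapply(reports, tidy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$raw_value, y = .data$node,
                                   fill = factor(.data$rank))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~ .data$scenario + .data$metric, scales = "free") +
    ggplot2::labs(x = "centrality", y = NULL, fill = "rank") +
    ggplot2::theme_minimal()
}
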