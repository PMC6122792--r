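#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a network as a node-link diagram
#'
#' Sugiyama layered layout (igraph) with edges drawn as arrows; when arc
#' strengths are supplied, edge width is proportional to strength. Node
#' color encodes the schema tier when a schema is given.
#'
#' @param graph A `bn_dag`.
#' @param schema Optional [cohort_schema()].
#' @param strengths Optional [arc_strengths()] table.
#' @return A ggplot object.
#' @export
plot_network <- function(graph, schema = NULL, strengths = NULL) {
  ig <- as_igraph(graph, schema = schema, strengths = strengths)
  lay <- igraph::layout_with_sugiyama(ig)$layout
  nodes <- tibble::tibble(name = graph$nodes,
                          x = lay[, 1], y = lay[, 2])
  if (!is.null(schema)) {
    nodes$tier <- schema$tier[match(nodes$name, schema$name)]
  } else {
    nodes$tier <- "node"
  }
  ed <- graph$edges
  p <- ggplot2::ggplot()
  if (nrow(ed)) {
    ed <- dplyr::mutate(
      ed,
      x = nodes$x[match(.data$from, nodes$name)],
      y = nodes$y[match(.data$from, nodes$name)],
      xend = nodes$x[match(.data$to, nodes$name)],
      yend = nodes$y[match(.data$to, nodes$name)])
    if (!is.null(strengths)) {
      idx <- match(paste(ed$from, ed$to),
                   paste(strengths$from, strengths$to))
      ed$strength <- strengths$strength[idx]
      p <- p + ggplot2::geom_segment(
        data = ed,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend, linewidth = .data$strength),
        arrow = grid::arrow(length = grid::unit(2.5, "mm")),
        color = "grey40") +
        ggplot2::scale_linewidth(range = c(0.2, 1.2), limits = c(0, 1))
    } else {
      p <- p + ggplot2::geom_segment(
        data = ed,
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend),
        arrow = grid::arrow(length = grid::unit(2.5, "mm")),
        color = "grey40")
    }
  }
  p +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$name, fill = .data$tier),
                        size = 3, alpha = 0.85) +
    ggplot2::scale_fill_brewer(palette = "Pastel1") +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
}

#' @rdname plot_network
#' @param object A `bn_averaged`.
#' @param ... Unused.
#' @method autoplot bn_averaged
#' @export
autoplot.bn_averaged <- function(object, schema = NULL, ...) {
  plot_network(object$graph, schema = schema, strengths = object$strengths) +
    ggplot2::labs(title = sprintf(
      "Averaged network (threshold %.2f, %d replicates)",
      object$threshold, object$replicates))
}

#' Arc-strength stability plot
#'
#' Lollipop chart of undirected arc strengths (one per unordered pair with
#' positive strength), annotated with the majority direction; a dashed line
#' marks a threshold when given.
#'
#' @param object An `bn_arc_strength` table.
#' @param threshold Optional threshold to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bn_arc_strength
#' @export
autoplot.bn_arc_strength <- function(object, threshold = NULL, ...) {
  nodes <- unique(c(object$from, object$to))
  df <- dplyr::filter(object,
                      match(.data$from, nodes) < match(.data$to, nodes),
                      .data$strength > 0)
  df <- dplyr::mutate(df, arc = paste(.data$from, "–", .data$to))
  df <- dplyr::arrange(df, .data$strength)
  df$arc <- factor(df$arc, levels = df$arc)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$strength, y = .data$arc)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$strength,
                                       yend = .data$arc), color = "grey70") +
    ggplot2::geom_point(ggplot2::aes(color = pmax(.data$direction,
                                                  1 - .data$direction))) +
    ggplot2::scale_color_viridis_c(name = "direction\nagreement",
                                   limits = c(0.5, 1)) +
    ggplot2::labs(x = "arc strength (bootstrap fraction)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' Propagation-contrast plot
#'
#' Point-range display of the conditional outcome mean and SD under each
#' condition of every query, faceted by outcome.
#'
#' @param object A `bn_propagation` results tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bn_propagation
#' @export
autoplot.bn_propagation <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, label = .data$label, outcome = .data$outcome,
                     condition = "A (baseline)", mean = .data$mean_a,
                     sd = .data$sd_a),
    dplyr::transmute(object, label = .data$label, outcome = .data$outcome,
                     condition = "B (changed)", mean = .data$mean_b,
                     sd = .data$sd_b))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$label, y = .data$mean,
                               color = .data$condition)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~outcome, scales = "free") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "outcome mean ± SD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
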