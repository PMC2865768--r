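#' Plot edge counts across the alpha sweep
#'
#' Shows the nesting behavior of the sweep: the number of inferred edges
#' grows monotonically as alpha relaxes.
#'
#' @param object A `grn_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grn_set
#' @export
autoplot.grn_set <- function(object, ...) {
  counts <- tibble::tibble(
    alpha = object$alphas,
    n_edges = vapply(object$alphas, function(a) {
      sum(object$edges$min_confidence >= a - 1e-12)
    }, numeric(1))
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$alpha, y = .data$n_edges)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(alpha), y = "inferred edges",
                  title = paste0("Network Type ", object$network_type,
                                 ": edges across the alpha sweep")) +
    ggplot2::theme_minimal()
}

#' Plot a signed regulatory network
#'
#' Force-directed layout; node color encodes the tumor regulation class
#' (up/down/unclassified), edge linetype the sign (solid activation,
#' dashed repression).
#'
#' @param object A `gene_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gene_network
#' @export
autoplot.gene_network <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(
    gene = igraph::V(g)$name,
    regulation = igraph::V(g)$regulation,
    x = xy[, 1], y = xy[, 2]
  )
  e <- object$edges
  pos <- stats::setNames(seq_len(nrow(nodes)), nodes$gene)
  edges <- tibble::tibble(
    x = nodes$x[pos[e$regulator]], y = nodes$y[pos[e$regulator]],
    xend = nodes$x[pos[e$target]], yend = nodes$y[pos[e$target]],
    sign = factor(ifelse(e$sign > 0, "activation", "repression"),
                  levels = c("activation", "repression"))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$sign),
      arrow = grid::arrow(length = grid::unit(2, "mm")), color = "grey40"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$regulation),
      size = 3
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$gene),
      vjust = -1, size = 3
    ) +
    ggplot2::scale_color_manual(values = c(up = "#c0392b", down = "#2980b9",
                                           unclassified = "grey60")) +
    ggplot2::labs(title = paste0("Type ", object$network_type,
                                 " network, alpha = ", format(object$alpha))) +
    ggplot2::theme_void()
}

#' Plot per-gene connection degrees across the sweep
#'
#' @param degrees Long tibble from [degree_table()].
#' @return A ggplot of total degree against alpha, one line per gene.
#' @export
plot_degree_sweep <- function(degrees) {
  if (!"degree" %in% names(degrees)) {
    degrees$degree <- degrees$indegree + degrees$outdegree
  }
  ggplot2::ggplot(degrees,
                  ggplot2::aes(x = as.numeric(.data$alpha), y = .data$degree,
                               group = .data$gene, color = .data$gene)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(alpha), y = "connection degree") +
    ggplot2::theme_minimal()
}
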