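#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a network sweep into its edge table
#'
#' @param x A `grn_set`.
#' @param ... Unused.
#' @return Tibble of edges with `regulator`, `target`, `sign`,
#'   `alpha_level`, `min_confidence`.
#' @method tidy grn_set
#' @export
tidy.grn_set <- function(x, ...) {
  out <- x$edges
  out$confidences <- NULL
  out
}

#' One-row summary of a network sweep
#'
#' @param x A `grn_set`.
#' @param ... Unused.
#' @return Tibble: `network_type`, `n_targets`, `n_edges` (at the most
#'   permissive alpha), `n_edges_strictest`, `alpha_min`, `alpha_max`.
#' @method glance grn_set
#' @export
glance.grn_set <- function(x, ...) {
  tibble::tibble(
    network_type = x$network_type,
    n_targets = sum(x$nodes$regulation != "unclassified"),
    n_edges = nrow(x$edges),
    n_edges_strictest = sum(x$edges$min_confidence >= max(x$alphas) - 1e-12),
    alpha_min = min(x$alphas),
    alpha_max = max(x$alphas)
  )
}

#' @rdname tidy.grn_set
#' @method tidy gene_network
#' @export
tidy.gene_network <- function(x, ...) {
  out <- x$edges
  out$confidences <- NULL
  out
}

#' @rdname glance.grn_set
#' @method glance gene_network
#' @export
glance.gene_network <- function(x, ...) {
  tibble::tibble(
    network_type = x$network_type,
    alpha = x$alpha,
    n_edges = nrow(x$edges),
    n_regulators = length(unique(x$edges$regulator)),
    n_targets = length(unique(x$edges$target))
  )
}
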