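#' Export edges as TSV
#'
#' Columns: regulator, target, sign, alpha_level (when present),
#' min_confidence, confidences (semicolon-joined per-block values).
#'
#' @param x A `grn_set`, `gene_network`, or edge tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges_tsv <- function(x, path) {
  e <- if (inherits(x, c("grn_set", "gene_network"))) x$edges else x
  out <- e
  if ("confidences" %in% names(out)) {
    out$confidences <- vapply(out$confidences, function(cc) {
      paste(fmt_shortest(cc), collapse = ";")
    }, character(1))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an edge TSV written by [write_edges_tsv()]
#'
#' @param path Input path.
#' @return Edge tibble with `confidences` as a list column.
#' @export
read_edges_tsv <- function(path) {
  e <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("confidences" %in% names(e)) {
    e$confidences <- lapply(strsplit(as.character(e$confidences), ";"), as.numeric)
  }
  e
}

#' Export a network in Cytoscape SIF format
#'
#' One line per edge: `regulator activates|represses target`
#' (tab-separated); positive edges activate, negative edges repress.
#'
#' @param x A `gene_network` (or `grn_set` plus `alpha`).
#' @param path Output path.
#' @param alpha Threshold when `x` is a `grn_set`.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path, alpha = NULL) {
  if (inherits(x, "grn_set")) {
    if (is.null(alpha)) rlang::abort("give `alpha` to pick a network from a sweep")
    x <- network_at(x, alpha)
  }
  e <- x$edges
  rel <- ifelse(e$sign > 0, "activates", "represses")
  writeLines(paste(e$regulator, rel, e$target, sep = "\t"), path)
  invisible(path)
}

#' Export a network as GraphML with node and edge attributes
#'
#' Nodes carry the `regulation` annotation (up/down/unclassified); edges
#' carry `sign`, `min_confidence` and, when present, `alpha_level`.
#'
#' @inheritParams write_sif
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path, alpha = NULL) {
  if (inherits(x, "grn_set")) {
    if (is.null(alpha)) rlang::abort("give `alpha` to pick a network from a sweep")
    x <- network_at(x, alpha)
  }
  g <- as_igraph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Convert a network to an igraph object
#'
#' @param x A `gene_network`.
#' @return A directed `igraph` graph with `regulation` node attributes
#'   and `sign`/`min_confidence`/`alpha_level` edge attributes.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "gene_network"))
  e <- x$edges
  nodes <- x$nodes[x$nodes$gene %in% unique(c(e$regulator, e$target,
                                              x$nodes$gene[x$nodes$regulation != "unclassified"])), ]
  edf <- data.frame(from = e$regulator, to = e$target, sign = e$sign,
                    min_confidence = e$min_confidence)
  if ("alpha_level" %in% names(e)) edf$alpha_level <- e$alpha_level
  vdf <- data.frame(name = nodes$gene, regulation = nodes$regulation)
  extra <- setdiff(unique(c(edf$from, edf$to)), vdf$name)
  if (length(extra) > 0) {
    vdf <- rbind(vdf, data.frame(name = extra, regulation = "unclassified"))
  }
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Write an asymmetry report as JSON
#'
#' @param report Tibble from [asymmetry_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Published connection-degree tables of the colon case study
#'
#' Long-format degree tables of the 18 identified colon-cancer marker
#' genes, as printed in the original case study: Type 1 (network among
#' the markers, 7 alpha levels) and Type 2 (genome-wide regulators onto
#' the markers, 5 alpha levels), each including the printed rounded
#' `"average"` column verbatim (arithmetic slips in the printed averages
#' and all original gene labels, e.g. `myosin` and `IPL1`, are preserved
#' as published).
#'
#' @param type `"type1"` or `"type2"`.
#' @return Tibble: `gene`, `regulation`, `alpha` (character; numeric
#'   levels plus `"average"`), `degree`, `indegree`, `outdegree`.
#' @export
colon_study_degrees <- function(type = c("type1", "type2")) {
  type <- match.arg(type)
  path <- system.file("extdata", paste0("colon_", type, "_degrees.tsv"),
                      package = "rulegrn", mustWork = TRUE)
  df <- readr::read_tsv(path, col_types = "cccii", progress = FALSE)
  df$outdegree <- df$degree - df$indegree
  df
}

#' The 18 identified colon-cancer marker genes
#'
#' @return Tibble: `gene`, `regulation` (`"up"`/`"down"` in tumor).
#' @export
colon_study_markers <- function() {
  path <- system.file("extdata", "colon_marker_genes.tsv",
                      package = "rulegrn", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}
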