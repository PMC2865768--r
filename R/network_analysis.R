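#' Connection-degree table across an alpha sweep
#'
#' Per target gene and sweep alpha: indegree (edges onto the gene),
#' outdegree (edges the gene sends to other target genes) and total
#' degree. The layout mirrors the printed degree tables of the colon
#' case study, where totals are printed with indegrees in parentheses.
#'
#' @param x A `grn_set` from [build_network()].
#' @param genes Genes to tabulate (default: the annotated identified
#'   genes, i.e. nodes not marked `"unclassified"`).
#' @return Long tibble: `gene`, `alpha`, `indegree`, `outdegree`,
#'   `degree`.
#' @export
degree_table <- function(x, genes = NULL) {
  if (is.null(genes)) {
    genes <- x$nodes$gene[x$nodes$regulation != "unclassified"]
  }
  rows <- purrr::map(x$alphas, function(a) {
    e <- x$edges[x$edges$min_confidence >= a - 1e-12, ]
    tibble::tibble(
      gene = genes,
      alpha = a,
      indegree = vapply(genes, function(g) sum(e$target == g), integer(1),
                        USE.NAMES = FALSE),
      outdegree = vapply(genes, function(g) sum(e$regulator == g), integer(1),
                         USE.NAMES = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$degree <- out$indegree + out$outdegree
  out
}

# Round half away from zero (the convention of the printed tables; R's
# round() would round halves to even).
round_half_up <- function(x) floor(x + 0.5)

#' Average degrees across the sweep
#'
#' @param degrees Long tibble from [degree_table()] (columns `gene`,
#'   `alpha`, `indegree`, `outdegree`, and optionally `degree`).
#' @return Per-gene tibble with exact means (`mean_*`) and half-up
#'   rounded integer views (`avg_*`) of degree, indegree and outdegree.
#' @export
degree_summary <- function(degrees) {
  if (!"degree" %in% names(degrees)) {
    degrees$degree <- degrees$indegree + degrees$outdegree
  }
  degrees |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      mean_degree = mean(.data$degree),
      mean_indegree = mean(.data$indegree),
      mean_outdegree = mean(.data$outdegree),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      avg_degree = round_half_up(.data$mean_degree),
      avg_indegree = round_half_up(.data$mean_indegree),
      avg_outdegree = round_half_up(.data$mean_outdegree)
    )
}

#' Count the eight regulatory patterns of a signed Type 1 network
#'
#' Activators are genes upregulated in tumor, suppressors downregulated.
#' For a suppressor S: `n1` counts negative out-edges to activators
#' (S suppressing activators), `n2` positive out-edges to suppressors,
#' `n5` negative in-edges from activators, `n6` positive in-edges from
#' suppressors. For an activator A: `n3` counts negative out-edges to
#' suppressors, `n4` positive out-edges to activators, `n7` negative
#' in-edges from suppressors, `n8` positive in-edges from activators.
#' On sign-consistent networks (edge sign positive iff the endpoints
#' share an annotation) `n1+n2+n3+n4` equals each gene's outdegree and
#' `n5+n6+n7+n8` its indegree; edges violating that consistency are
#' reported in `n_other_out`/`n_other_in` with a warning.
#'
#' @param network A `gene_network` from [network_at()] (or a `grn_set`,
#'   in which case `alpha` must be given).
#' @param alpha Threshold when `network` is a `grn_set`.
#' @return Tibble: `gene`, `regulation`, `n1` ... `n8`, `n_other_out`,
#'   `n_other_in`.
#' @export
pattern_counts <- function(network, alpha = NULL) {
  if (inherits(network, "grn_set")) {
    if (is.null(alpha)) rlang::abort("give `alpha` to pick a network from a sweep")
    network <- network_at(network, alpha)
  }
  edges <- network$edges
  nodes <- network$nodes
  reg_of <- stats::setNames(nodes$regulation, nodes$gene)
  genes <- nodes$gene[nodes$regulation %in% c("up", "down")]
  if (nrow(edges) > 0) {
    if (anyNA(edges$sign)) rlang::abort("pattern counting requires signed edges")
    missing <- setdiff(unique(c(edges$regulator, edges$target)), genes)
    if (length(missing) > 0) {
      rlang::abort(paste0("unannotated nodes in network: ",
                          paste(missing, collapse = ", ")))
    }
  }
  out <- tibble::tibble(
    gene = genes, regulation = unname(reg_of[genes]),
    n1 = 0L, n2 = 0L, n3 = 0L, n4 = 0L, n5 = 0L, n6 = 0L, n7 = 0L, n8 = 0L,
    n_other_out = 0L, n_other_in = 0L
  )
  idx <- stats::setNames(seq_along(genes), genes)
  bump <- function(g, col) {
    out[[col]][idx[[g]]] <<- out[[col]][idx[[g]]] + 1L
  }
  for (i in seq_len(nrow(edges))) {
    r <- edges$regulator[i]; t <- edges$target[i]; s <- edges$sign[i]
    rc <- reg_of[[r]]; tc <- reg_of[[t]]
    # outgoing view (patterns 1-4), then incoming view (patterns 5-8)
    if (rc == "down" && tc == "up" && s == -1) bump(r, "n1")
    else if (rc == "down" && tc == "down" && s == 1) bump(r, "n2")
    else if (rc == "up" && tc == "down" && s == -1) bump(r, "n3")
    else if (rc == "up" && tc == "up" && s == 1) bump(r, "n4")
    else bump(r, "n_other_out")
    if (tc == "down" && rc == "up" && s == -1) bump(t, "n5")
    else if (tc == "down" && rc == "down" && s == 1) bump(t, "n6")
    else if (tc == "up" && rc == "down" && s == -1) bump(t, "n7")
    else if (tc == "up" && rc == "up" && s == 1) bump(t, "n8")
    else bump(t, "n_other_in")
  }
  if (any(out$n_other_out > 0) || any(out$n_other_in > 0)) {
    rlang::warn("some edges have signs inconsistent with their endpoint annotations; counted under n_other_*")
  }
  out
}

#' One-tailed paired t-test (x greater than y)
#'
#' Paired t statistic on the differences `x - y`, `df = n - 1`, upper
#' one-tailed p-value. Used for within-group out- vs indegree
#' comparisons.
#'
#' @param x,y Paired numeric vectors of equal length `>= 2`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_x`,
#'   `mean_y`.
#' @export
paired_t_one_tailed <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    rlang::abort("paired test needs two equal-length vectors of size >= 2")
  }
  d <- x - y
  if (stats::sd(d) == 0) rlang::abort("degenerate paired test: zero-variance differences")
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "greater")
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' One-tailed Welch t-test (mean of x greater than mean of y)
#'
#' Unequal-variance two-sample t statistic with Welch-Satterthwaite
#' degrees of freedom, upper one-tailed p-value. Used for between-group
#' indegree comparisons.
#'
#' @param x,y Numeric vectors, each of length `>= 2`, not both constant.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_x`,
#'   `mean_y`.
#' @export
welch_t_one_tailed <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    rlang::abort("each group needs at least 2 values")
  }
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    rlang::abort("degenerate test: both groups are constant")
  }
  ht <- stats::t.test(x, y, alternative = "greater", var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Degree-asymmetry report between up- and downregulated genes
#'
#' For each alpha the report aggregates group mean in/outdegrees and
#' three one-tailed tests: within downregulated genes out > in (paired),
#' within upregulated genes in > out (paired), and between groups
#' upregulated indegree > downregulated indegree (Welch). When the
#' degree table carries an `"average"` pseudo-alpha row (the printed
#' tables' rounded average column) it is reported like any other level.
#' Degenerate tests are returned as `NA` with a `note`.
#'
#' @param degrees A `grn_set` (degrees are computed via [degree_table()])
#'   or a long degree tibble with columns `gene`, `alpha`, `indegree`,
#'   `outdegree` (`alpha` may be character to accommodate `"average"`).
#' @param annotations Tibble with `gene` and `regulation`
#'   (`"up"`/`"down"`); taken from the `grn_set` nodes when omitted.
#' @return Tibble, one row per alpha level: group means, Welch and
#'   paired test statistics and p-values, and `note`.
#' @export
asymmetry_report <- function(degrees, annotations = NULL) {
  if (inherits(degrees, "grn_set")) {
    if (is.null(annotations)) annotations <- degrees$nodes
    degrees <- degree_table(degrees)
  }
  if (is.null(annotations)) rlang::abort("gene annotations are required")
  degrees$regulation <- NULL # the annotation table is authoritative
  df <- dplyr::inner_join(degrees, annotations[c("gene", "regulation")], by = "gene")
  df <- df[df$regulation %in% c("up", "down"), ]
  lv <- unique(as.character(df$alpha))
  rows <- purrr::map(lv, function(a) {
    d <- df[as.character(df$alpha) == a, ]
    up <- d[d$regulation == "up", ]; dn <- d[d$regulation == "down", ]
    note <- character(0)
    safe <- function(expr) tryCatch(expr, error = function(e) {
      note <<- c(note, conditionMessage(e))
      tibble::tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                     mean_x = NA_real_, mean_y = NA_real_)
    })
    welch <- safe(welch_t_one_tailed(up$indegree, dn$indegree))
    pdn <- safe(paired_t_one_tailed(dn$outdegree, dn$indegree))
    pup <- safe(paired_t_one_tailed(up$indegree, up$outdegree))
    tibble::tibble(
      alpha = a,
      mean_in_up = mean(up$indegree), mean_in_down = mean(dn$indegree),
      mean_out_up = mean(up$outdegree), mean_out_down = mean(dn$outdegree),
      welch_t = welch$statistic, welch_df = welch$df, welch_p = welch$p_value,
      paired_down_out_gt_in_t = pdn$statistic, paired_down_out_gt_in_p = pdn$p_value,
      paired_up_in_gt_out_t = pup$statistic, paired_up_in_gt_out_p = pup$p_value,
      note = if (length(note) == 0) NA_character_ else paste(note, collapse = "; ")
    )
  })
  dplyr::bind_rows(rows)
}
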