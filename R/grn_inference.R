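#' Default alpha sweep for network construction
#'
#' @return `c(1, 0.95, 0.9, 0.85, 0.8, 0.75, 0.7)`.
#' @export
alpha_sweep_default <- function() c(1, 0.95, 0.9, 0.85, 0.8, 0.75, 0.7)

# Best single class-supervised MDL cut of a continuous gene; NULL when no
# cut is accepted. When the recursion accepts several cuts the single cut
# with the largest whole-data information gain (smallest value on ties)
# is used to binarize.
best_class_cut <- function(values, labels) {
  cuts <- find_cuts(values, labels)
  if (length(cuts) == 0L) return(NULL)
  if (length(cuts) == 1L) return(cuts)
  e0 <- class_entropy(labels)
  n <- length(values)
  gains <- vapply(cuts, function(ct) {
    lo <- values <= ct
    e0 - (sum(lo) * class_entropy(labels[lo]) +
            sum(!lo) * class_entropy(labels[!lo])) / n
  }, numeric(1))
  cuts[which(gains == max(gains))[1]]
}

#' Annotate genes as up- or downregulated in the tumor class
#'
#' Each gene is binarized at its class-supervised MDL cut; a gene is
#' `"up"` when tumor samples fall on the high side more often than
#' non-tumor samples, `"down"` in the opposite case, and
#' `"unclassified"` when no cut is accepted (or the two sides tie).
#'
#' @param x A `decision_table` with continuous genes and the class as
#'   decision attribute.
#' @param genes Genes to annotate (default all condition attributes).
#' @param tumor_class Decision value treated as the disease class;
#'   defaults to `"Tumor"` when present, otherwise the first sorted value.
#' @return Tibble: `gene`, `regulation` (`"up"`, `"down"`,
#'   `"unclassified"`).
#' @export
annotate_genes <- function(x, genes = condition_attributes(x), tumor_class = NULL) {
  d <- as.character(decision_values(x))
  if (is.null(tumor_class)) {
    tumor_class <- if ("Tumor" %in% d) "Tumor" else sort(unique(d))[1]
  }
  is_t <- d == tumor_class
  if (!any(is_t) || all(is_t)) rlang::abort("both classes must be present")
  reg <- vapply(genes, function(g) {
    cut <- best_class_cut(x[[g]], d)
    if (is.null(cut)) return("unclassified")
    hi <- x[[g]] > cut
    p_t <- mean(hi[is_t]); p_n <- mean(hi[!is_t])
    if (p_t > p_n) "up" else if (p_t < p_n) "down" else "unclassified"
  }, character(1))
  tibble::tibble(gene = genes, regulation = unname(reg))
}

#' Sign of a binary regulator-target rule pair
#'
#' `+1` when the regulator's low interval implies target `Down` and its
#' high interval implies `Up` (co-directional regulation); `-1` for the
#' mirrored mapping; `NA` when both intervals imply the same target level
#' (no discrimination). Regulators with more than two intervals are
#' signed only in `mode = "monotone"`, and only when the interval-order
#' to level mapping is monotone (a run of `Down` followed by a run of
#' `Up`, or vice versa).
#'
#' @param rules Tibble from [induce_rules()] for one regulator onto a
#'   binary `Down`/`Up` target, one row per interval in interval order.
#' @param mode `"binary"` (default; >2 intervals give `NA`) or
#'   `"monotone"`.
#' @return `+1`, `-1`, or `NA_real_`.
#' @export
edge_sign <- function(rules, mode = c("binary", "monotone")) {
  mode <- match.arg(mode)
  lv <- rules$consequent
  k <- length(lv)
  if (k < 2L) return(NA_real_)
  if (k == 2L) {
    if (lv[1] == "Down" && lv[2] == "Up") return(1)
    if (lv[1] == "Up" && lv[2] == "Down") return(-1)
    return(NA_real_)
  }
  if (mode == "binary") return(NA_real_)
  r <- rle(lv)
  if (length(r$values) != 2L) return(NA_real_)
  if (identical(r$values, c("Down", "Up"))) 1 else if (identical(r$values, c("Up", "Down"))) -1 else NA_real_
}

# Per-candidate determination profile onto a binarized target. The
# discretization of every candidate is supervised by the binarized target
# and is independent of alpha, so one profile serves the whole sweep.
target_profile <- function(x, target, candidates, sign_mode = "binary") {
  d <- as.character(decision_values(x))
  cut0 <- best_class_cut(x[[target]], d)
  if (is.null(cut0)) {
    rlang::abort(paste0("target '", target, "' has no class-supervised cut ",
                        "and cannot be binarized"))
  }
  tgt <- ifelse(x[[target]] <= cut0, "Down", "Up")
  rows <- purrr::map(candidates, function(g) {
    cuts <- find_cuts(x[[g]], tgt)
    n_int <- length(cuts) + 1L
    if (n_int == 1L) {
      return(tibble::tibble(regulator = g, target = target, n_intervals = 1L,
                            sign = NA_real_, min_confidence = NA_real_,
                            confidences = list(numeric(0)), barred = "all"))
    }
    ints <- assign_intervals(x[[g]], cuts)
    blocks <- split(tgt, ints, drop = TRUE)
    conf <- vapply(blocks, function(b) max(table(b)) / length(b), numeric(1))
    lev <- vapply(blocks, function(b) names(which.max(table(b))), character(1))
    rules <- tibble::tibble(attribute = g, interval = names(blocks),
                            consequent = lev, confidence = conf)
    sgn <- edge_sign(rules, mode = sign_mode)
    barred <- if (n_int > 2L && sign_mode == "binary") "multi_interval"
              else if (is.na(sgn)) "sign_undefined" else NA_character_
    tibble::tibble(regulator = g, target = target, n_intervals = n_int,
                   sign = sgn, min_confidence = min(conf),
                   confidences = list(unname(conf)), barred = barred)
  })
  dplyr::bind_rows(rows)
}

#' Infer signed regulators of one target gene
#'
#' The target is binarized (`Down`/`Up`) at its class-supervised MDL cut;
#' every candidate gene is then re-discretized supervised by the binary
#' target, and an edge `candidate -> target` is emitted iff the candidate
#' has at least two intervals, every one of its blocks yields a rule at
#' confidence `>= alpha` (i.e. `gamma_candidate(target, alpha) = 1`), and
#' the rule pattern defines a sign. Single-interval (`'All'`) candidates
#' are barred: they determine any alpha-skewed target trivially without
#' discriminating anything.
#'
#' @param x A `decision_table` with continuous genes and the class as
#'   decision attribute.
#' @param target The target gene (must be binarizable).
#' @param alpha Confidence threshold in `(0.5, 1]`.
#' @param candidates Candidate regulators (default: all other genes).
#' @param sign_mode `"binary"` (default) suppresses regulators with more
#'   than two intervals; `"monotone"` signs them when the interval-to-
#'   level mapping is monotone.
#' @param strict_direction When `TRUE`, an edge is dropped if the reverse
#'   determination also holds at `alpha` (the target, binarized, also
#'   determines the candidate binarized at its own class cut).
#' @return Tibble of edges: `regulator`, `target`, `sign`,
#'   `min_confidence`, `confidences` (list column, per interval block).
#' @export
infer_regulators <- function(x, target, alpha, candidates = NULL,
                             sign_mode = c("binary", "monotone"),
                             strict_direction = FALSE) {
  check_alpha(alpha)
  sign_mode <- match.arg(sign_mode)
  if (is.null(candidates)) candidates <- condition_attributes(x)
  candidates <- setdiff(candidates, target)
  prof <- target_profile(x, target, candidates, sign_mode)
  edges <- prof[!is.na(prof$sign) & prof$min_confidence >= alpha - 1e-12, ]
  if (strict_direction && nrow(edges) > 0) {
    keep <- vapply(edges$regulator, function(g) {
      !reverse_determines(x, regulator = g, target = target, alpha = alpha,
                          sign_mode = sign_mode)
    }, logical(1))
    edges <- edges[keep, ]
  }
  edges$barred <- NULL
  edges
}

# TRUE when the binarized target also determines the candidate g
# (binarized at g's own class-supervised cut) at confidence alpha.
reverse_determines <- function(x, regulator, target, alpha, sign_mode = "binary") {
  d <- as.character(decision_values(x))
  if (is.null(best_class_cut(x[[regulator]], d))) return(FALSE)
  prof <- target_profile(x, regulator, target, sign_mode)
  nrow(prof) == 1L && !is.na(prof$sign) && prof$min_confidence >= alpha - 1e-12
}

#' Build regulatory networks across an alpha sweep
#'
#' For each target the candidate discretization (supervised by the
#' binarized target) is computed once and reused across the sweep, which
#' guarantees the nesting property: the edge set at a larger alpha is a
#' subgraph, with identical signs, of the edge set at any smaller alpha.
#' Network Type 1 takes targets = candidates = the identified genes;
#' Type 2 takes all genes as candidates.
#'
#' @param x A `decision_table` with continuous genes and the class as
#'   decision attribute.
#' @param targets Genes treated as decision attributes in turn.
#' @param candidates Candidate regulators (default: all condition genes).
#' @param alphas Sweep thresholds, each in `(0.5, 1]`; default
#'   [alpha_sweep_default()].
#' @param sign_mode,strict_direction Passed to [infer_regulators()].
#' @param tumor_class Passed to [annotate_genes()].
#' @return A `grn_set`: list with `edges` (tibble: `regulator`, `target`,
#'   `sign`, `min_confidence`, `alpha_level` = largest sweep alpha at
#'   which the edge holds, `confidences`), `nodes` (gene, regulation),
#'   `alphas`, `network_type`, and `suppressed` (per-target counts of
#'   barred 'All' candidates and sign-undefined suppressions).
#' @export
build_network <- function(x, targets, candidates = NULL,
                          alphas = alpha_sweep_default(),
                          sign_mode = c("binary", "monotone"),
                          strict_direction = FALSE, tumor_class = NULL) {
  sign_mode <- match.arg(sign_mode)
  if (length(targets) == 0L) rlang::abort("at least one target gene is required")
  for (a in alphas) check_alpha(a)
  alphas <- sort(unique(alphas), decreasing = TRUE)
  if (is.null(candidates)) candidates <- condition_attributes(x)
  network_type <- if (setequal(targets, candidates)) 1L else 2L
  alpha_min <- min(alphas)

  profs <- purrr::map(targets, function(tg) {
    tryCatch(
      target_profile(x, tg, setdiff(candidates, tg), sign_mode),
      error = function(e) {
        rlang::warn(paste0("skipping target '", tg, "': ", conditionMessage(e)))
        NULL
      }
    )
  })
  prof <- dplyr::bind_rows(profs)
  if (nrow(prof) == 0L) {
    prof <- tibble::tibble(regulator = character(0), target = character(0),
                           n_intervals = integer(0), sign = numeric(0),
                           min_confidence = numeric(0), confidences = list(),
                           barred = character(0))
  }
  suppressed <- prof |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(
      n_candidates = dplyr::n(),
      n_barred_all = sum(.data$barred == "all", na.rm = TRUE),
      n_multi_interval = sum(.data$barred == "multi_interval", na.rm = TRUE),
      n_sign_undefined = sum(.data$barred == "sign_undefined", na.rm = TRUE),
      .groups = "drop"
    )
  edges <- prof[!is.na(prof$sign) & prof$min_confidence >= alpha_min - 1e-12, ]
  if (strict_direction && nrow(edges) > 0) {
    keep <- vapply(seq_len(nrow(edges)), function(i) {
      !reverse_determines(x, edges$regulator[i], edges$target[i],
                          alpha = alpha_min, sign_mode = sign_mode)
    }, logical(1))
    edges <- edges[keep, ]
  }
  edges$alpha_level <- vapply(edges$min_confidence, function(m) {
    max(alphas[alphas <= m + 1e-12])
  }, numeric(1))
  edges$barred <- NULL
  edges <- edges[order(edges$target, edges$regulator), ]

  identified <- if (network_type == 1L) targets else unique(c(targets, candidates[candidates %in% targets]))
  ann <- annotate_genes(x, genes = targets, tumor_class = tumor_class)
  other <- setdiff(unique(c(edges$regulator, candidates)), targets)
  nodes <- dplyr::bind_rows(
    ann,
    tibble::tibble(gene = other, regulation = "unclassified")
  )
  structure(
    list(edges = tibble::as_tibble(edges), nodes = nodes, alphas = alphas,
         network_type = network_type, suppressed = suppressed),
    class = "grn_set"
  )
}

#' @export
print.grn_set <- function(x, ...) {
  cat("# Gene regulatory network sweep (Type ", x$network_type, ")\n",
      "# alphas: ", paste(x$alphas, collapse = ", "), "\n", sep = "")
  for (a in x$alphas) {
    cat("#   alpha = ", format(a), ": ",
        sum(x$edges$min_confidence >= a - 1e-12), " edges\n", sep = "")
  }
  invisible(x)
}

#' Extract the network at one alpha value
#'
#' @param x A `grn_set` from [build_network()].
#' @param alpha Threshold; edges with every block confidence `>= alpha`
#'   are retained.
#' @return A `gene_network`: list with `edges`, `nodes`, `alpha`,
#'   `network_type`.
#' @export
network_at <- function(x, alpha) {
  check_alpha(alpha)
  edges <- x$edges[x$edges$min_confidence >= alpha - 1e-12, ]
  structure(
    list(edges = edges, nodes = x$nodes, alpha = alpha,
         network_type = x$network_type),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("# Gene regulatory network (Type ", x$network_type, ", alpha = ",
      format(x$alpha), "): ", nrow(x$edges), " edges, ",
      nrow(x$nodes), " annotated nodes\n", sep = "")
  invisible(x)
}
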