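#' Alpha positive region of a decision partition
#'
#' A block `Y` of the condition partition enters the positive region iff
#' some decision class `X` satisfies `|Y n X| / |Y| >= alpha`. With
#' `alpha > 0.5` at most one class can qualify, so membership reduces to
#' the majority-class purity test.
#'
#' @param p_partition Condition-attribute [equivalence_partition()].
#' @param d_partition Decision-attribute partition over the same samples.
#' @param alpha Purity threshold in `(0.5, 1]`.
#' @return Character vector of sample IDs in the positive region.
#' @export
alpha_positive_region <- function(p_partition, d_partition, alpha) {
  check_alpha(alpha)
  if (!setequal(p_partition$universe, d_partition$universe)) {
    rlang::abort("partitions are over different sample universes")
  }
  pos <- character(0)
  for (y in p_partition$blocks) {
    purity <- max(vapply(d_partition$blocks,
                         function(x) length(intersect(y, x)) / length(y),
                         numeric(1)))
    if (purity >= alpha - 1e-12) pos <- c(pos, y)
  }
  sort(pos)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0.5 || alpha > 1) {
    rlang::abort("alpha must lie in (0.5, 1]")
  }
  invisible(alpha)
}

#' Alpha depended degree of a condition subset
#'
#' `gamma_P(D, alpha)` is the fraction of samples in the alpha positive
#' region of the partition induced by `P` with respect to the decision
#' partition. `gamma = 1` means `P` determines the decision at purity
#' tolerance `alpha`; `alpha = 1` recovers the classical rough-set
#' depended degree. `gamma` is non-increasing in `alpha`.
#'
#' @param x A discretized `decision_table`.
#' @param attrs Condition attribute subset `P`.
#' @param alpha Purity threshold in `(0.5, 1]`.
#' @return One-row tibble: `alpha`, `gamma`, `n_samples`, `n_positive`,
#'   and `positive_region` (list column of sample IDs).
#' @export
alpha_depended_degree <- function(x, attrs, alpha) {
  check_alpha(alpha)
  p_part <- equivalence_partition(x, attrs)
  d_part <- equivalence_partition(x, decision_attribute(x))
  pos <- alpha_positive_region(p_part, d_part, alpha)
  tibble::tibble(
    alpha = alpha,
    gamma = length(pos) / nrow(x),
    n_samples = nrow(x),
    n_positive = length(pos),
    positive_region = list(pos)
  )
}

#' Induce single-attribute decision rules at confidence alpha
#'
#' For each equivalence class (interval) of `g`, a rule
#' `g = interval => decision = value` is emitted iff some decision value
#' covers at least a fraction `alpha` of the block; its confidence is that
#' fraction. With `alpha > 0.5` at most one rule per block exists.
#'
#' @param x A discretized `decision_table`.
#' @param g A condition attribute name.
#' @param alpha Confidence threshold in `(0.5, 1]`.
#' @return Tibble of rules: `attribute`, `interval`, `consequent`,
#'   `n_antecedent`, `support_antecedent`, `confidence`, ordered by
#'   interval. Blocks with no qualifying decision value yield no row.
#' @export
induce_rules <- function(x, g, alpha) {
  check_alpha(alpha)
  if (!g %in% condition_attributes(x)) {
    rlang::abort(paste0("'", g, "' is not a condition attribute"))
  }
  v <- x[[g]]
  if (is.numeric(v)) rlang::abort("rule induction requires a discretized attribute")
  d <- as.character(decision_values(x))
  lv <- if (is.factor(v)) levels(v)[levels(v) %in% as.character(v)] else unique(as.character(v))
  rows <- purrr::map(lv, function(int) {
    in_block <- as.character(v) == int
    n <- sum(in_block)
    tab <- table(d[in_block])
    best <- which.max(tab)
    conf <- as.numeric(tab[best]) / n
    if (conf < alpha - 1e-12) return(NULL)
    tibble::tibble(
      attribute = g, interval = int, consequent = names(tab)[best],
      n_antecedent = n, support_antecedent = n / nrow(x), confidence = conf
    )
  })
  dplyr::bind_rows(rows)
}

#' Human-readable rule text
#'
#' Renders rules as `if <attr> = <interval> then <decision> = <value>
#' (NN% confidence)`.
#'
#' @param rules A tibble from [induce_rules()].
#' @param decision Decision attribute name used in the text.
#' @return Character vector, one line per rule.
#' @export
format_rules <- function(rules, decision = "class") {
  sprintf("if %s = %s then %s = %s (%s%% confidence)",
          rules$attribute, rules$interval, decision, rules$consequent,
          fmt_shortest(round(rules$confidence * 100, 1)))
}

#' Select genes that fully determine the decision at tolerance alpha
#'
#' A gene is selected iff every one of its equivalence classes passes the
#' alpha purity test, i.e. `gamma_gene(D, alpha) = 1`. Single-interval
#' (`'All'`) genes can only qualify when one decision value alone reaches
#' frequency `alpha`; such genes are flagged `degenerate` (they carry no
#' discrimination and are barred from acting as regulators downstream).
#'
#' @param x A discretized `decision_table`.
#' @param alpha Threshold in `(0.5, 1]`.
#' @return Tibble: `gene`, `n_intervals`, `min_confidence`, `degenerate`.
#' @export
select_genes <- function(x, alpha) {
  check_alpha(alpha)
  d <- as.character(decision_values(x))
  rows <- purrr::map(condition_attributes(x), function(g) {
    v <- as.character(x[[g]])
    confs <- vapply(split(d, v), function(dd) max(table(dd)) / length(dd), numeric(1))
    if (min(confs) < alpha - 1e-12) return(NULL)
    tibble::tibble(gene = g, n_intervals = length(confs),
                   min_confidence = min(confs), degenerate = length(confs) == 1L)
  })
  dplyr::bind_rows(rows)
}

#' Classify a sample with a set of decision rules
#'
#' Fires the rule whose antecedent the sample satisfies; abstains
#' (returns `NA`) when no rule matches. When several rules fire with
#' different consequents the winner is chosen by highest confidence, then
#' larger antecedent support, then lexicographically smallest consequent.
#'
#' @param rules Tibble from [induce_rules()] (possibly several attributes).
#' @param newdata Named list or one-row data frame of attribute values;
#'   raw numeric values are mapped to intervals when `scheme` is given,
#'   otherwise interval labels are expected.
#' @param scheme Optional `discretization_scheme` used to discretize raw
#'   values.
#' @return The winning consequent, or `NA_character_` on abstention.
#' @export
classify <- function(rules, newdata, scheme = NULL) {
  if (nrow(rules) == 0L) return(NA_character_)
  newdata <- as.list(newdata)
  fired <- vapply(seq_len(nrow(rules)), function(i) {
    a <- rules$attribute[i]
    if (!a %in% names(newdata)) return(FALSE)
    val <- newdata[[a]]
    if (is.numeric(val) && !is.null(scheme)) {
      val <- as.character(assign_intervals(val, scheme$cuts[[a]]))
    }
    as.character(val) == rules$interval[i]
  }, logical(1))
  if (!any(fired)) return(NA_character_)
  hits <- rules[fired, ]
  hits <- hits[order(-hits$confidence, -hits$support_antecedent, hits$consequent), ]
  hits$consequent[1]
}

#' Leave-one-out cross-validation of a one-gene rule classifier
#'
#' Per fold the held-out sample is removed, the gene is re-discretized
#' against the class on the remaining samples (no information leakage),
#' rules are induced at `alpha`, and the held-out sample is classified
#' with the fold's own cuts. Abstentions count as errors; folds whose
#' training class labels collapse to a single value are counted as errors
#' and reported in `n_degenerate`.
#'
#' @param x A `decision_table` with continuous `gene` and a binary
#'   categorical decision attribute.
#' @param gene Condition attribute used for classification.
#' @param alpha Rule confidence threshold in `(0.5, 1]`.
#' @return One-row tibble: `accuracy`, `n`, `n_correct`, `n_abstained`,
#'   `n_degenerate`.
#' @export
loocv <- function(x, gene, alpha) {
  check_alpha(alpha)
  if (nrow(x) < 3L) rlang::abort("LOOCV needs at least 3 samples")
  v <- x[[gene]]
  if (!is.numeric(v)) rlang::abort("LOOCV expects a continuous gene")
  d <- as.character(decision_values(x))
  if (length(unique(d)) != 2L) rlang::abort("LOOCV expects a binary class")
  n <- length(d)
  correct <- 0L; abstained <- 0L; degenerate <- 0L
  for (i in seq_len(n)) {
    tr_v <- v[-i]; tr_d <- d[-i]
    if (length(unique(tr_d)) < 2L) {
      degenerate <- degenerate + 1L
      next
    }
    cuts <- find_cuts(tr_v, tr_d)
    ints <- as.character(assign_intervals(tr_v, cuts))
    tr <- new_decision_table(
      tibble::tibble(sample = as.character(seq_along(tr_v)), !!gene := ints,
                     class = tr_d),
      decision = "class", conditions = gene
    )
    rules <- induce_rules(tr, gene, alpha)
    pred <- classify(rules, stats::setNames(list(v[i]), gene),
                     scheme = new_discretization_scheme(
                       stats::setNames(list(cuts), gene), "class"))
    if (is.na(pred)) abstained <- abstained + 1L
    else if (pred == d[i]) correct <- correct + 1L
  }
  tibble::tibble(accuracy = correct / n, n = n, n_correct = correct,
                 n_abstained = abstained, n_degenerate = degenerate)
}
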