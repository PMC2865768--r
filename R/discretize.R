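#' Shannon entropy of a label multiset, in bits
#'
#' @param labels Non-empty vector of categorical decision values.
#' @return Entropy in bits, in `[0, log2(#classes)]`.
#' @export
#' @examples
#' class_entropy(c("T", "T", "N", "N")) # 1
#' class_entropy(c("T", "T", "T"))      # 0
class_entropy <- function(labels) {
  if (length(labels) == 0L) rlang::abort("cannot compute entropy of an empty label set")
  p <- tabulate(factor(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Midpoints between adjacent distinct values whose label sets differ
# (Fayyad-Irani boundary points). `values` need not be sorted.
boundary_candidates <- function(values, labels) {
  ord <- order(values)
  v <- values[ord]
  l <- as.character(labels[ord])
  dv <- unique(v)
  if (length(dv) < 2L) return(numeric(0))
  labsets <- lapply(dv, function(x) unique(l[v == x]))
  cuts <- numeric(0)
  for (i in seq_len(length(dv) - 1L)) {
    a <- labsets[[i]]; b <- labsets[[i + 1L]]
    pure_same <- length(a) == 1L && length(b) == 1L && a == b
    if (!pure_same) cuts <- c(cuts, (dv[i] + dv[i + 1L]) / 2)
  }
  cuts
}

# MDL stopping rule: accept a split iff
#   gain > log2(N-1)/N + delta/N,
#   delta = log2(3^k - 2) - (k*E(S) - k1*E(S1) - k2*E(S2))
mdl_accepts <- function(gain, n, labels, left, right) {
  k <- length(unique(labels))
  k1 <- length(unique(left))
  k2 <- length(unique(right))
  delta <- log2(3^k - 2) -
    (k * class_entropy(labels) - k1 * class_entropy(left) - k2 * class_entropy(right))
  gain > log2(n - 1) / n + delta / n
}

#' Supervised MDL-stopped cut-point search
#'
#' Recursive entropy minimization over boundary midpoints: at each level
#' the candidate cut with the largest information gain (ties broken toward
#' the smallest cut value) is tested against the MDL criterion; if
#' accepted, both sides are split recursively. Returns an empty vector
#' when no cut is accepted (the attribute is then labeled `'All'`).
#'
#' @param values Numeric attribute values.
#' @param labels Aligned decision values.
#' @return Strictly increasing numeric cut points (possibly empty).
#' @export
#' @examples
#' find_cuts(c(1, 2, 3, 4), c("T", "T", "N", "N")) # 2.5
find_cuts <- function(values, labels) {
  if (length(values) != length(labels)) {
    rlang::abort("values and labels must be aligned")
  }
  if (length(values) == 0L) rlang::abort("at least one sample is required")
  if (anyNA(values) || anyNA(labels)) rlang::abort("missing values are not allowed")
  rec <- function(v, l) {
    if (length(unique(l)) < 2L) return(numeric(0))
    cands <- boundary_candidates(v, l)
    if (length(cands) == 0L) return(numeric(0))
    n <- length(v)
    e0 <- class_entropy(l)
    gains <- vapply(cands, function(ct) {
      lo <- v <= ct
      e0 - (sum(lo) * class_entropy(l[lo]) + sum(!lo) * class_entropy(l[!lo])) / n
    }, numeric(1))
    best <- which(gains == max(gains))[1] # candidates ascend, so smallest cut wins ties
    ct <- cands[best]
    lo <- v <= ct
    if (!mdl_accepts(gains[best], n, l, l[lo], l[!lo])) return(numeric(0))
    c(rec(v[lo], l[lo]), ct, rec(v[!lo], l[!lo]))
  }
  rec(values, labels)
}

# Shortest decimal representation that round-trips to x exactly.
fmt_shortest <- function(x) {
  vapply(x, function(xi) {
    for (d in 1:17) {
      s <- format(xi, digits = d, scientific = FALSE, trim = TRUE)
      if (as.numeric(s) == xi) return(s)
    }
    format(xi, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Interval labels for a set of cut points
#'
#' Dialect: no cuts gives the single label `'All'`; one cut `c` gives
#' `'(-inf-c)'` (meaning `<= c`) and `'(c-inf)'` (meaning `> c`); further
#' cuts insert middle labels `'(a-b)'` (meaning `a < value <= b`).
#'
#' @param cuts Strictly increasing numeric vector (possibly empty).
#' @return Character vector of `length(cuts) + 1` labels.
#' @export
interval_labels <- function(cuts) {
  if (length(cuts) == 0L) return("All")
  if (is.unsorted(cuts, strictly = TRUE)) {
    rlang::abort("cut points must be strictly increasing")
  }
  s <- fmt_shortest(cuts)
  bounds <- c("-inf", s, "inf")
  paste0("(", bounds[-length(bounds)], "-", bounds[-1], ")")
}

#' Map continuous values to interval labels
#'
#' Left-closed at each cut: a value exactly at a cut belongs to the
#' interval below it. Returns an ordered factor whose levels follow
#' interval order.
#'
#' @param values Numeric values.
#' @param cuts Strictly increasing cut points (possibly empty).
#' @return Ordered factor of interval labels.
#' @export
assign_intervals <- function(values, cuts) {
  labs <- interval_labels(cuts)
  if (length(cuts) == 0L) {
    return(factor(rep("All", length(values)), levels = labs, ordered = TRUE))
  }
  idx <- findInterval(values, cuts, left.open = TRUE) + 1L
  factor(labs[idx], levels = labs, ordered = TRUE)
}

#' Discretize every condition attribute of a decision table
#'
#' Cut points are found per attribute by [find_cuts()], supervised by the
#' *current* decision attribute -- so re-running after promoting a gene to
#' decision attribute generally yields different cuts. Attributes with no
#' accepted cut are labeled `'All'` for every sample.
#'
#' @param x A `decision_table` with a categorical decision attribute and
#'   continuous condition attributes.
#' @return A `decision_table` whose condition columns are ordered factors
#'   of interval labels, carrying the `discretization_scheme` in the
#'   `scheme` attribute (see [disc_scheme()]).
#' @export
discretize_table <- function(x) {
  if (is.numeric(decision_values(x))) {
    rlang::abort("the decision attribute must be categorical before discretization")
  }
  labels <- as.character(decision_values(x))
  data <- tibble::as_tibble(x)
  conds <- condition_attributes(x)
  cuts <- vector("list", length(conds))
  names(cuts) <- conds
  for (g in conds) {
    if (!is.numeric(data[[g]])) {
      rlang::abort(paste0("condition attribute '", g, "' is not continuous"))
    }
    cg <- find_cuts(data[[g]], labels)
    cuts[[g]] <- cg
    data[[g]] <- assign_intervals(data[[g]], cg)
  }
  out <- new_decision_table(data, decision = decision_attribute(x),
                            conditions = conds, meta = attr(x, "meta"))
  attr(out, "attr_index") <- attr(x, "attr_index")
  attr(out, "scheme") <- new_discretization_scheme(cuts, decision_attribute(x))
  out
}

new_discretization_scheme <- function(cuts, decision) {
  structure(list(cuts = cuts, decision = decision),
            class = "discretization_scheme")
}

#' Discretization scheme of a discretized table
#'
#' @param x A table returned by [discretize_table()].
#' @return The `discretization_scheme`: per-attribute cut points plus the
#'   decision attribute that supervised them.
#' @export
disc_scheme <- function(x) attr(x, "scheme", exact = TRUE)

#' @export
print.discretization_scheme <- function(x, ...) {
  n_cut <- sum(lengths(x$cuts) > 0)
  cat("# Discretization scheme supervised by '", x$decision, "': ",
      n_cut, "/", length(x$cuts), " attributes with cuts\n", sep = "")
  invisible(x)
}

#' Serialize a discretization scheme to TSV (and back)
#'
#' Two columns: attribute, comma-joined cut points (empty for 'All').
#' Cut values are written as shortest round-trip decimals, so schemes
#' round-trip losslessly.
#'
#' @param scheme A `discretization_scheme`.
#' @param path File path.
#' @return `write_scheme()`: `path` invisibly; `read_scheme()`: the scheme.
#' @export
write_scheme <- function(scheme, path) {
  out <- tibble::tibble(
    attribute = names(scheme$cuts),
    cuts = vapply(scheme$cuts, function(cc) {
      if (length(cc) == 0L) "" else paste(fmt_shortest(cc), collapse = ",")
    }, character(1)),
    decision = scheme$decision
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccc", na = character(), progress = FALSE)
  cuts <- lapply(df$cuts, function(s) {
    if (is.na(s) || s == "") numeric(0) else as.numeric(strsplit(s, ",")[[1]])
  })
  names(cuts) <- df$attribute
  new_discretization_scheme(cuts, df$decision[1])
}
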