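#' Decision tables for rule-based network inference
#'
#' A decision table is a samples-by-attributes tibble with one designated
#' decision attribute (the tumor/normal class label, or -- during network
#' inference -- a binarized target gene) and a set of condition attributes
#' (genes). The first column, `sample`, holds unique sample identifiers.
#'
#' @param data A data frame with a `sample` column.
#' @param decision Name of the decision attribute column.
#' @param conditions Character vector of condition attribute columns.
#'   Defaults to every column other than `sample`, the decision attribute
#'   and `meta`.
#' @param meta Character vector of metadata columns that belong to neither
#'   the condition set nor the decision attribute (e.g. the original class
#'   label once a gene has been promoted to decision attribute).
#'
#' @return A `decision_table`, a tibble subclass carrying the attribute
#'   roles as attributes.
#' @export
#' @examples
#' df <- tibble::tibble(
#'   sample = c("s1", "s2", "s3", "s4"),
#'   g1 = c(1.2, 3.1, 0.8, 2.9),
#'   class = c("Tumor", "Normal", "Tumor", "Normal")
#' )
#' as_decision_table(df, decision = "class")
as_decision_table <- function(data, decision, conditions = NULL, meta = character()) {
  data <- tibble::as_tibble(data)
  if (!"sample" %in% names(data)) {
    rlang::abort("decision tables need a `sample` column of sample identifiers")
  }
  if (is.null(conditions)) {
    conditions <- setdiff(names(data), c("sample", decision, meta))
  }
  new_decision_table(data, decision = decision, conditions = conditions, meta = meta)
}

new_decision_table <- function(data, decision, conditions, meta = character()) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c("sample", decision, conditions, meta), names(data))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("columns not present in table: ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (length(decision) != 1L) rlang::abort("exactly one decision attribute is required")
  if (decision %in% conditions) {
    rlang::abort("the decision attribute cannot also be a condition attribute")
  }
  if (anyDuplicated(conditions)) rlang::abort("duplicate condition attribute names")
  ids <- as.character(data$sample)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    rlang::abort(paste0("duplicate sample IDs: ", paste(dup, collapse = ", ")))
  }
  if (nrow(data) < 2L) rlang::abort("a decision table needs at least 2 samples")
  for (a in c(decision, conditions)) {
    bad <- which(is.na(data[[a]]))
    if (length(bad) > 0) {
      rlang::abort(paste0("missing value for sample '", ids[bad[1]],
                          "', attribute '", a, "'"))
    }
  }
  data$sample <- ids
  structure(
    data,
    decision = decision,
    conditions = conditions,
    meta = meta,
    class = c("decision_table", class(tibble::tibble()))
  )
}

#' Attribute roles of a decision table
#'
#' @param x A `decision_table`.
#' @return `decision_attribute()` the decision column name;
#'   `condition_attributes()` the condition column names;
#'   `decision_values()` the decision column values.
#' @export
decision_attribute <- function(x) attr(x, "decision", exact = TRUE)

#' @rdname decision_attribute
#' @export
condition_attributes <- function(x) attr(x, "conditions", exact = TRUE)

#' @rdname decision_attribute
#' @export
decision_values <- function(x) x[[decision_attribute(x)]]

#' @export
print.decision_table <- function(x, ...) {
  cat("# Decision table: ", nrow(x), " samples, ",
      length(condition_attributes(x)), " condition attributes, decision = '",
      decision_attribute(x), "'\n", sep = "")
  NextMethod()
}

#' Read an expression decision table from delimited text
#'
#' Canonical layout: rows are samples, the first column holds sample IDs,
#' gene columns follow, and one column (`label_column`) carries the class
#' label. Gene-major files (rows are genes, columns are samples, the first
#' column holds gene IDs and one row holds the labels) are transposed with
#' `orientation = "genes"`. The delimiter is taken from the file extension
#' (`.csv` is comma, anything else tab).
#'
#' Gene attributes also receive 0-based positional indices (stored in the
#' `attr_index` attribute), the numbering used to label non-identified
#' genes in genome-wide network exports.
#'
#' @param path Path to a delimited text file with a header.
#' @param label_column Name of the class-label column (or, for gene-major
#'   files, the label row's ID). Default `"class"`.
#' @param orientation `"samples"` (rows are samples; default) or `"genes"`.
#' @return A [as_decision_table()] with the class as decision attribute.
#' @export
read_expression_table <- function(path, label_column = "class",
                                  orientation = c("samples", "genes")) {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE)
  if (ncol(raw) < 2L) rlang::abort("expected at least an ID column and one attribute")
  if (orientation == "genes") {
    ids <- as.character(raw[[1]])
    if (anyDuplicated(ids)) rlang::abort("duplicate gene IDs in gene-major file")
    mat <- t(as.matrix(raw[-1]))
    out <- tibble::as_tibble(mat, .name_repair = "minimal")
    names(out) <- ids
    raw <- dplyr::bind_cols(tibble::tibble(sample = colnames(raw)[-1]), out)
  } else {
    names(raw)[1] <- "sample"
  }
  if (!label_column %in% names(raw)) {
    rlang::abort(paste0("label column '", label_column, "' not found"))
  }
  genes <- setdiff(names(raw), c("sample", label_column))
  samples <- as.character(raw$sample)
  for (g in genes) {
    v <- raw[[g]]
    blank <- which(is.na(v) | trimws(v) == "")
    if (length(blank) > 0) {
      rlang::abort(paste0("missing value for sample '", samples[blank[1]],
                          "', attribute '", g, "'"))
    }
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      rlang::abort(paste0("non-numeric expression value '", v[bad[1]],
                          "' for sample '", samples[bad[1]],
                          "', attribute '", g, "'"))
    }
    raw[[g]] <- num
  }
  tbl <- new_decision_table(raw, decision = label_column, conditions = genes)
  attr(tbl, "attr_index") <- stats::setNames(seq_along(genes) - 1L, genes)
  tbl
}

#' Write a decision table as delimited text
#'
#' Canonical orientation (rows are samples, class last); the delimiter
#' follows the file extension as in [read_expression_table()]. Values
#' round-trip exactly (shortest round-trip decimals).
#'
#' @param x A `decision_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  cols <- c("sample", condition_attributes(x), attr(x, "meta"), decision_attribute(x))
  out <- tibble::as_tibble(x)[cols]
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Promote a gene to decision attribute
#'
#' Replaces the current decision attribute (kept as metadata) by a gene
#' binarized at a single cut point: values `<=` the cut become `"Down"`,
#' values above it `"Up"` (the left-closed interval dialect). The gene is
#' removed from the condition set.
#'
#' @param x A `decision_table` with continuous condition attributes.
#' @param gene A condition attribute name.
#' @param cut A single numeric cut point, or a [discretization scheme]
#'   [discretize_table()] holding exactly one cut for `gene`.
#' @return A `decision_table` with `gene` as binary decision attribute.
#' @export
set_decision_attribute <- function(x, gene, cut) {
  if (!gene %in% condition_attributes(x)) {
    rlang::abort(paste0("'", gene, "' is not a condition attribute"))
  }
  if (inherits(cut, "discretization_scheme")) cut <- cut$cuts[[gene]]
  if (is.null(cut) || length(cut) == 0L) {
    rlang::abort(paste0("gene '", gene, "' cannot serve as decision attribute: ",
                        "no cut point (single 'All' interval)"))
  }
  if (length(cut) != 1L || !is.finite(cut)) {
    rlang::abort("exactly one finite cut point is required to binarize a gene")
  }
  v <- x[[gene]]
  if (!is.numeric(v)) rlang::abort("the target gene must be continuous")
  data <- tibble::as_tibble(x)
  data[[gene]] <- ifelse(v <= cut, "Down", "Up")
  old_decision <- decision_attribute(x)
  new_decision_table(
    data,
    decision = gene,
    conditions = setdiff(condition_attributes(x), gene),
    meta = union(attr(x, "meta"), old_decision)
  )
}

#' Partition samples into equivalence classes
#'
#' Two samples fall in the same block iff they agree on every inducing
#' attribute. Attributes must be discretized (categorical); partitioning a
#' continuous column is refused.
#'
#' @param x A `decision_table`.
#' @param attrs Attribute names (conditions or the decision attribute).
#' @return An `equivalence_partition`: a list with `blocks` (list of
#'   sample-ID vectors), `attrs`, and `universe` (all sample IDs).
#' @export
#' @examples
#' df <- tibble::tibble(
#'   sample = as.character(1:6),
#'   g = c("lo", "lo", "lo", "hi", "hi", "hi"),
#'   class = c("T", "T", "N", "T", "N", "N")
#' )
#' tbl <- as_decision_table(df, decision = "class")
#' equivalence_partition(tbl, "g")
equivalence_partition <- function(x, attrs) {
  if (length(attrs) == 0L) rlang::abort("at least one inducing attribute is required")
  known <- c(condition_attributes(x), decision_attribute(x), attr(x, "meta"))
  bad <- setdiff(attrs, known)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown attributes: ", paste(bad, collapse = ", ")))
  }
  for (a in attrs) {
    if (is.numeric(x[[a]])) {
      rlang::abort(paste0("partition requires discretized values; '", a,
                          "' is continuous"))
    }
  }
  key <- do.call(paste, c(lapply(attrs, function(a) as.character(x[[a]])),
                          sep = "\r"))
  blocks <- unname(split(x$sample, factor(key, levels = unique(key))))
  structure(
    list(blocks = blocks, attrs = attrs, universe = x$sample),
    class = "equivalence_partition"
  )
}

#' @export
print.equivalence_partition <- function(x, ...) {
  cat("# Equivalence partition on {", paste(x$attrs, collapse = ", "), "}: ",
      length(x$blocks), " blocks over ", length(x$universe), " samples\n",
      sep = "")
  invisible(x)
}
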