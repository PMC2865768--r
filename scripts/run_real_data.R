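#!/usr/bin/env Rscript
# Run the full pipeline on the original colon-cancer microarray dataset
# (62 samples x 2000 genes, Tumor/Normal), which is NOT bundled with this
# package. Supply it yourself as a delimited text file in the canonical
# layout (rows = samples, first column = sample IDs, gene columns, one
# class column), e.g. converted from the public Affymetrix matrix, and
# point --input at it:
#
#   Rscript scripts/run_real_data.R --input colon.tsv --labels class --out results/colon
#
# The script selects fully class-determining genes at alpha = 1, infers
# the Type 1 network among the 18 annotated marker genes (where present
# in your gene naming) and the Type 2 genome-wide network onto them,
# and writes edge lists, SIF/GraphML exports, degree tables and the
# asymmetry report. Quantities that depend on the original data (rule
# confidences, LOOCV accuracy, absolute degree tables) can only be
# reproduced this way.
suppressPackageStartupMessages(library(rulegrn))

args <- commandArgs(trailingOnly = TRUE)
opt <- function(key, default = NULL) {
  i <- which(args == paste0("--", key))
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
input <- opt("input")
if (is.null(input)) stop("--input <expression table> is required", call. = FALSE)
out <- opt("out", "results/colon")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tbl <- read_expression_table(input, label_column = opt("labels", "class"))
disc <- discretize_table(tbl)

sel <- select_genes(disc, alpha = 1)
readr::write_tsv(sel, file.path(out, "selected_genes_alpha1.tsv"))

markers <- colon_study_markers()
targets <- intersect(markers$gene, condition_attributes(tbl))
if (length(targets) == 0) {
  message("none of the 18 annotated marker genes match your column names; ",
          "using the alpha = 1 selected, non-degenerate genes as targets")
  targets <- sel$gene[!sel$degenerate]
}
if (length(targets) == 0) stop("no usable target genes", call. = FALSE)

for (type in c(1L, 2L)) {
  cands <- if (type == 1L) targets else condition_attributes(tbl)
  net <- build_network(tbl, targets = targets, candidates = cands)
  dir_t <- file.path(out, paste0("type", type))
  dir.create(dir_t, showWarnings = FALSE)
  write_edges_tsv(net, file.path(dir_t, "edges.tsv"))
  readr::write_tsv(net$nodes, file.path(dir_t, "nodes.tsv"))
  for (a in net$alphas) {
    write_sif(net, file.path(dir_t, sprintf("network_alpha%s.sif", format(a))), alpha = a)
  }
  degrees <- degree_table(net)
  readr::write_tsv(degrees, file.path(dir_t, "degrees.tsv"))
  write_report_json(asymmetry_report(net), file.path(dir_t, "report.json"))
  if (type == 1L) {
    readr::write_tsv(pattern_counts(net, alpha = 0.8), file.path(dir_t, "patterns_alpha0.8.tsv"))
  }
  message("Type ", type, " network written under ", dir_t)
}

# Single-gene LOOCV for the strongest selected genes
top <- head(sel$gene[!sel$degenerate], 5)
if (length(top) > 0) {
  acc <- dplyr::bind_rows(lapply(top, function(g) {
    dplyr::bind_cols(tibble::tibble(gene = g), loocv(tbl, g, alpha = 0.8))
  }))
  readr::write_tsv(acc, file.path(out, "loocv_alpha0.8.tsv"))
}
message("done; outputs under ", out)
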