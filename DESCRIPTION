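Package: rulegrn
Title: Directed Signed Gene Regulatory Networks from Soft Decision Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Infers directed, signed gene regulatory networks from two-class
    expression decision tables using rough-set decision rules. Continuous
    expression values are discretized by supervised, MDL-stopped entropy
    partitioning; class-discriminative genes are selected by the alpha
    depended degree (a confidence-relaxed rough-set dependency); and
    regulator-target edges are induced by treating each selected gene in
    turn as the decision attribute, with edge signs read off the
    low/high-to-down/up rule mapping. Includes network degree and
    regulatory-pattern analyses with one-tailed t-test comparisons, a
    rule-based classifier with leave-one-out cross-validation, a synthetic
    data generator with planted signed edges for benchmarking, Cytoscape
    (SIF/GraphML) exporters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
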