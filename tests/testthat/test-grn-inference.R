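# Construct a table whose candidate blocks have exactly the worked
# purities: candidate low block 30 samples (25 Down, 5 Up), high block
# 20 samples (5 Down, 15 Up); the target's continuous value equals its
# intended binary level and the class label is aligned with it, so the
# class-supervised binarization cut is unambiguous.
worked_block_table <- function() {
  tgt_low <- c(rep(0, 25), rep(1, 5))   # low candidate block: 5/6 Down
  tgt_high <- c(rep(0, 5), rep(1, 15))  # high candidate block: 3/4 Up
  tgt <- c(tgt_low, tgt_high)
  as_decision_table(tibble::tibble(
    sample = as.character(1:50),
    cand = c(rep(1, 30), rep(2, 20)),
    tgt = tgt,
    class = ifelse(tgt == 0, "Tumor", "Normal")
  ), decision = "class")
}

test_that("edge emission follows the per-block confidence threshold", {
  tbl <- worked_block_table()
  e80 <- infer_regulators(tbl, "tgt", 0.8, candidates = "cand")
  expect_equal(nrow(e80), 0) # 3/4-pure block fails at alpha = 0.8
  e75 <- infer_regulators(tbl, "tgt", 0.75, candidates = "cand")
  expect_equal(nrow(e75), 1)
  expect_equal(e75$sign, 1)
  expect_equal(sort(e75$confidences[[1]]), c(3 / 4, 5 / 6))
})

test_that("single-interval candidates are barred even when gamma = 1 trivially", {
  tbl <- worked_block_table()
  data <- tibble::as_tibble(tbl)
  data$flat <- 1 # constant: 'All' under any supervision
  tbl2 <- as_decision_table(data, decision = "class")
  net <- build_network(tbl2, targets = "tgt", candidates = c("cand", "flat"),
                       alphas = c(0.75, 0.7))
  expect_false("flat" %in% net$edges$regulator)
  expect_equal(net$suppressed$n_barred_all, 1L)
})

test_that("edge signs map low/high rule patterns to +1 / -1 / undefined", {
  mk_rules <- function(cons) tibble::tibble(
    attribute = "g", interval = c("(-inf-1)", "(1-inf)"),
    consequent = cons, confidence = c(0.95, 0.95)
  )
  expect_equal(edge_sign(mk_rules(c("Down", "Up"))), 1)
  expect_equal(edge_sign(mk_rules(c("Up", "Down"))), -1)
  expect_true(is.na(edge_sign(mk_rules(c("Up", "Up")))))
  # >2 intervals: undefined in binary mode, monotone mode signs runs
  r3 <- tibble::tibble(attribute = "g",
                       interval = c("(-inf-1)", "(1-2)", "(2-inf)"),
                       consequent = c("Down", "Down", "Up"),
                       confidence = rep(0.9, 3))
  expect_true(is.na(edge_sign(r3)))
  expect_equal(edge_sign(r3, mode = "monotone"), 1)
  r3$consequent <- c("Down", "Up", "Down")
  expect_true(is.na(edge_sign(r3, mode = "monotone")))
})

test_that("a noiseless planted edge is recovered with sign +1 at alpha = 1", {
  cfg <- synthetic_config(n_samples = 60, tumor_fraction = 0.5,
                          n_background = 5, n_markers_down = 1,
                          n_markers_up = 0, marker_shift = 6,
                          n_edges = 1, edge_signs = 1, noise_sd = 0, seed = 3)
  sim <- generate_synthetic(cfg)
  e <- infer_regulators(sim$table, "TG01", 1)
  expect_true(any(e$regulator == "MKD01" & e$sign == 1))
})

test_that("a target without a class-supervised cut cannot be binarized", {
  withr::with_seed(5, {
    tbl <- as_decision_table(tibble::tibble(
      sample = as.character(1:20),
      noise = rnorm(20),
      g = rnorm(20),
      class = rep(c("Tumor", "Normal"), 10)
    ), decision = "class")
    expect_error(infer_regulators(tbl, "noise", 0.9), "cannot be binarized")
    # in a sweep the degenerate target is skipped, not fatal
    expect_warning(net <- build_network(tbl, targets = c("noise"),
                                        candidates = "g", alphas = 0.9),
                   "skipping target")
    expect_equal(nrow(net$edges), 0)
  })
})

test_that("edge sets nest across the sweep with identical signs", {
  for (seed in c(101, 202)) {
    sim <- generate_synthetic(synthetic_config(
      n_samples = 60, tumor_fraction = 0.5, n_background = 20, seed = seed))
    net <- build_network(sim$table, targets = sim$truth$target,
                         alphas = c(0.95, 0.9, 0.8, 0.7))
    alphas <- sort(net$alphas)
    for (i in seq_along(alphas)[-1]) {
      lo <- network_at(net, alphas[i - 1])$edges # smaller alpha: superset
      hi <- network_at(net, alphas[i])$edges
      key <- function(e) paste(e$regulator, e$target, e$sign)
      expect_true(all(key(hi) %in% key(lo)))
    }
  }
})

test_that("Type 1 edges equal the Type 2 subset with identified-gene regulators", {
  sim <- generate_synthetic(synthetic_config(
    n_samples = 60, tumor_fraction = 0.5, n_background = 15,
    n_markers_down = 4, n_markers_up = 2, n_edges = 3, seed = 77))
  identified <- c(sim$truth$regulator, sim$truth$target)
  t1 <- build_network(sim$table, targets = identified, candidates = identified,
                      alphas = c(0.9, 0.8))
  t2 <- build_network(sim$table, targets = identified,
                      candidates = condition_attributes(sim$table),
                      alphas = c(0.9, 0.8))
  expect_equal(t1$network_type, 1L)
  expect_equal(t2$network_type, 2L)
  key <- function(e) sort(paste(e$regulator, e$target, e$sign, e$min_confidence))
  sub2 <- t2$edges[t2$edges$regulator %in% identified, ]
  expect_equal(key(t1$edges), key(sub2))
})

test_that("negating the target flips every edge sign and nothing else", {
  tbl <- worked_block_table()
  fwd <- build_network(tbl, targets = "tgt", candidates = "cand", alphas = 0.75)
  data <- tibble::as_tibble(tbl)
  data$tgt <- -data$tgt
  rev <- build_network(as_decision_table(data, decision = "class"),
                       targets = "tgt", candidates = "cand", alphas = 0.75)
  expect_equal(nrow(rev$edges), nrow(fwd$edges))
  expect_equal(rev$edges$sign, -fwd$edges$sign)
  expect_equal(rev$edges$min_confidence, fwd$edges$min_confidence)
})

test_that("strict direction mode drops mutually determining pairs", {
  # target is an exact copy of the regulator: determination is symmetric
  cfg <- synthetic_config(n_samples = 40, tumor_fraction = 0.5,
                          n_background = 5, n_markers_down = 1,
                          n_markers_up = 0, marker_shift = 6,
                          n_edges = 1, edge_signs = 1, noise_sd = 0, seed = 13)
  sim <- generate_synthetic(cfg)
  default <- infer_regulators(sim$table, "TG01", 0.95)
  expect_true("MKD01" %in% default$regulator)
  strict <- infer_regulators(sim$table, "TG01", 0.95, strict_direction = TRUE)
  expect_false("MKD01" %in% strict$regulator)
})

test_that("tidy, glance and the exporters expose the same edge set", {
  tbl <- worked_block_table()
  net <- build_network(tbl, targets = "tgt", candidates = "cand",
                       alphas = c(0.8, 0.75))
  td <- tidy(net)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(glance(net)$n_edges, 1)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_edges_tsv(net, f)
  back <- read_edges_tsv(f)
  expect_equal(back$regulator, net$edges$regulator)
  expect_equal(back$confidences, net$edges$confidences)

  fsif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, fsif, alpha = 0.75)
  expect_equal(readLines(fsif), "cand\tactivates\ttgt")

  fgml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, fgml, alpha = 0.75)
  g <- igraph::read_graph(fgml, format = "graphml")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$sign, 1)
  expect_setequal(igraph::V(g)$name, c("cand", "tgt"))

  p <- autoplot(net)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(network_at(net, 0.75))
  expect_s3_class(p2, "ggplot")
})
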