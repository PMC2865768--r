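test_that("positive region and depended degree reproduce the worked two-block case", {
  tbl <- two_block_table() # lo: 5 Tumor + 1 Normal; hi: 1 Tumor + 3 Normal
  pp <- equivalence_partition(tbl, "g")
  dp <- equivalence_partition(tbl, "class")

  pos <- alpha_positive_region(pp, dp, 0.8)
  expect_equal(sort(pos), sort(tbl$sample[tbl$g == "lo"])) # 5/6 passes, 3/4 fails
  expect_equal(alpha_depended_degree(tbl, "g", 0.8)$gamma, 0.6)
  expect_equal(alpha_depended_degree(tbl, "g", 0.75)$gamma, 1.0)

  # alpha = 1 keeps only blocks wholly inside one decision class
  pure <- disc_table(data.frame(g = c("a", "a", "b", "b"),
                                class = c("T", "T", "N", "N")))
  expect_equal(alpha_depended_degree(pure, "g", 1)$gamma, 1.0)

  # one block = U with a 50/50 decision split: empty at alpha = 0.8
  half <- disc_table(data.frame(g = rep("All", 4), class = c("T", "T", "N", "N")))
  expect_equal(alpha_depended_degree(half, "g", 0.8)$gamma, 0)

  expect_error(check_ok <- alpha_positive_region(pp, equivalence_partition(
    disc_table(data.frame(g = c("a", "b"), class = c("T", "N"))), "class"), 0.8),
    "different sample universes")
  expect_error(alpha_depended_degree(tbl, "g", 0.5), "alpha")
  expect_error(alpha_depended_degree(tbl, "g", 1.1), "alpha")
})

test_that("gamma at alpha = 1 equals the classical set-inclusion depended degree", {
  withr::with_seed(51, {
    for (rep in 1:30) {
      tbl <- random_disc_table(n = sample(4:12, 1), p = sample(1:3, 1))
      attrs <- sample(setdiff(condition_attributes(tbl), character(0)),
                      sample(seq_along(condition_attributes(tbl)), 1))
      got <- alpha_depended_degree(tbl, attrs, 1)$gamma
      # classical oracle: a block is positive iff it is a subset of some class
      keyP <- do.call(paste, c(lapply(attrs, function(a) tbl[[a]]), sep = "|"))
      d <- decision_values(tbl)
      n_pos <- 0
      for (kp in unique(keyP)) {
        y <- which(keyP == kp)
        if (length(unique(d[y])) == 1) n_pos <- n_pos + length(y)
      }
      expect_equal(got, n_pos / nrow(tbl))
    }
  })
})

test_that("gamma is non-increasing in alpha on random tables", {
  alphas <- c(0.7, 0.75, 0.8, 0.85, 0.9, 0.95, 1)
  withr::with_seed(61, {
    for (rep in 1:25) {
      tbl <- random_disc_table(n = sample(4:12, 1), p = 2)
      g <- vapply(alphas, function(a) alpha_depended_degree(tbl, "a1", a)$gamma,
                  numeric(1))
      expect_true(all(diff(g) <= 1e-12))
    }
  })
})

test_that("rule induction yields the expected rules and respects alpha", {
  # low block 96% Down (24/25), high block 100% Up
  tbl <- disc_table(data.frame(
    g = c(rep("(-inf-1048)", 25), rep("(1048-inf)", 10)),
    class = c(rep("Down", 24), "Up", rep("Up", 10))
  ))
  r <- induce_rules(tbl, "g", 0.95)
  expect_equal(nrow(r), 2)
  expect_equal(r$consequent, c("Down", "Up"))
  expect_equal(r$confidence, c(0.96, 1.0))
  expect_true(all(r$confidence >= 0.95))
  expect_match(format_rules(r, "g249")[1], "if g = \\(-inf-1048\\) then g249 = Down \\(96% confidence\\)")

  # a 3/4 block produces no rule at alpha = 0.8
  tbl34 <- disc_table(data.frame(g = rep("lo", 4), class = c("T", "T", "T", "N")))
  expect_equal(nrow(induce_rules(tbl34, "g", 0.8)), 0)

  # an 'All' attribute with a 90%-dominant class yields the degenerate rule
  tbl_all <- disc_table(data.frame(g = rep("All", 10),
                                   class = c(rep("Tumor", 9), "Normal")))
  r_all <- induce_rules(tbl_all, "g", 0.8)
  expect_equal(nrow(r_all), 1)
  expect_equal(r_all$consequent, "Tumor")
  expect_equal(r_all$confidence, 0.9)

  expect_error(induce_rules(tbl, "missing", 0.8), "not a condition attribute")
})

test_that("gamma and rule sets match the brute-force oracle on random tables", {
  alphas <- c(0.7, 0.8, 0.9, 1)
  withr::with_seed(71, {
    for (rep in 1:40) {
      tbl <- random_disc_table(n = sample(3:12, 1), p = sample(1:4, 1))
      df <- as.data.frame(tbl)
      for (a in alphas) {
        attrs <- condition_attributes(tbl)
        P <- sample(attrs, sample(length(attrs), 1))
        expect_equal(alpha_depended_degree(tbl, P, a)$gamma,
                     oracle_gamma(df, P, "class", a)$gamma)
        g <- sample(attrs, 1)
        got <- induce_rules(tbl, g, a)
        want <- oracle_rules(df, g, "class", a)
        expect_equal(nrow(got), nrow(want))
        if (nrow(got) > 0) {
          got_o <- got[order(got$interval, got$consequent), ]
          expect_equal(as.character(got_o$interval), want$interval)
          expect_equal(got_o$consequent, want$consequent)
          expect_equal(got_o$confidence, want$confidence)
        }
      }
    }
  })
})

test_that("gene selection keeps exactly the fully determining genes", {
  tbl <- disc_table(data.frame(
    perfect = c("a", "a", "b", "b", "a", "b"),
    mixed = c("x", "x", "x", "y", "y", "y"),   # blocks 2/3 and 2/3 pure
    flat = rep("All", 6),
    class = c("T", "T", "N", "N", "T", "N")
  ))
  sel1 <- select_genes(tbl, 1)
  expect_equal(sel1$gene, "perfect")
  expect_false(sel1$degenerate)

  # 2/3-pure blocks qualify at alpha = 2/3-ish but not at 0.8
  expect_false("mixed" %in% select_genes(tbl, 0.8)$gene)

  # degenerate 'All' gene qualifies only when one class dominates at alpha
  skew <- disc_table(data.frame(flat = rep("All", 10),
                                class = c(rep("T", 9), "N")))
  s <- select_genes(skew, 0.9)
  expect_equal(s$gene, "flat")
  expect_true(s$degenerate)
  expect_equal(nrow(select_genes(skew, 0.95)), 0)
})

test_that("classification fires matching rules, resolves conflicts, abstains otherwise", {
  rules <- tibble::tibble(
    attribute = c("g1", "g2"),
    interval = c("(-inf-2)", "(-inf-5)"),
    consequent = c("Tumor", "Normal"),
    n_antecedent = c(10L, 8L),
    support_antecedent = c(0.5, 0.4),
    confidence = c(0.9, 0.95)
  )
  scheme <- structure(list(cuts = list(g1 = 2, g2 = 5), decision = "class"),
                      class = "discretization_scheme")
  # only rule 1 fires
  expect_equal(classify(rules, list(g1 = 1.5, g2 = 7), scheme), "Tumor")
  # both fire: higher confidence wins
  expect_equal(classify(rules, list(g1 = 1.5, g2 = 3), scheme), "Normal")
  # no rule fires: abstain
  expect_true(is.na(classify(rules, list(g1 = 3, g2 = 7), scheme)))
  # confidence tie resolves by larger antecedent support
  rules2 <- rules
  rules2$confidence <- c(0.9, 0.9)
  expect_equal(classify(rules2, list(g1 = 1.5, g2 = 3), scheme), "Tumor")
})

test_that("LOOCV re-discretizes per fold, counts abstentions and degenerate folds as errors", {
  # perfectly separable marker at n = 20
  withr::with_seed(81, {
    cls <- rep(c("T", "N"), each = 10)
    tbl <- as_decision_table(tibble::tibble(
      sample = as.character(1:20),
      g = ifelse(cls == "T", rnorm(20, 0), rnorm(20, 10)),
      class = cls
    ), decision = "class")
    expect_equal(loocv(tbl, "g", 0.8)$accuracy, 1.0)
  })

  # n = 3 with a degenerate (single-class) training fold: that fold is an
  # error, the other two classify correctly, accuracy 2/3
  t3 <- as_decision_table(tibble::tibble(
    sample = c("a", "b", "c"), g = c(1, 2, 9), class = c("A", "A", "B")
  ), decision = "class")
  res <- loocv(t3, "g", 0.8)
  expect_equal(res$accuracy, 2 / 3)
  expect_equal(res$n_degenerate, 1L)

  # class-independent gene at n = 20 balanced: no fold finds reliable
  # rules, so folds abstain and (abstentions counting as errors) accuracy
  # collapses far below chance
  withr::with_seed(91, {
    res <- lapply(1:15, function(i) {
      tbl <- as_decision_table(tibble::tibble(
        sample = as.character(1:20),
        g = rnorm(20),
        class = rep(c("T", "N"), 10)
      ), decision = "class")
      loocv(tbl, "g", 0.8)
    })
    accs <- vapply(res, function(r) r$accuracy, numeric(1))
    abst <- vapply(res, function(r) r$n_abstained, integer(1))
    expect_lt(mean(accs), 0.3)
    expect_gt(mean(abst / 20), 0.5)
  })

  expect_error(loocv(t3[1:2, ], "g", 0.8), "at least 3")
})
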