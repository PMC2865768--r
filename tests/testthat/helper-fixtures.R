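# In-code fixtures shared across tests.

# Decision table from a plain data frame of categorical columns.
disc_table <- function(df, decision = "class") {
  if (!"sample" %in% names(df)) df$sample <- as.character(seq_len(nrow(df)))
  as_decision_table(tibble::as_tibble(df), decision = decision)
}

# The worked two-block table: block lo = 5 Tumor + 1 Normal, block hi =
# 1 Tumor + 3 Normal (10 samples).
two_block_table <- function() {
  disc_table(data.frame(
    g = c(rep("lo", 6), rep("hi", 4)),
    class = c(rep("Tumor", 5), "Normal", "Tumor", rep("Normal", 3))
  ))
}

# Random discretized table: n samples, p condition attributes with 1-3
# categorical levels each, binary decision.
random_disc_table <- function(n, p) {
  df <- data.frame(sample = as.character(seq_len(n)))
  for (j in seq_len(p)) {
    k <- sample(1:3, 1)
    df[[paste0("a", j)]] <- sample(paste0("v", seq_len(k)), n, replace = TRUE)
  }
  df$class <- sample(c("T", "N"), n, replace = TRUE)
  disc_table(df)
}

# Miniature continuous table in the canonical on-disk layout (rows are
# samples, class last), written to a temp file.
write_mini_expression <- function(path, n = 12, seed = 7) {
  withr::with_seed(seed, {
    cls <- rep(c("Tumor", "Normal"), length.out = n)
    df <- data.frame(
      sample = paste0("s", seq_len(n)),
      gA = rnorm(n, ifelse(cls == "Tumor", 0, 4)),
      gB = rnorm(n, 2),
      gC = rnorm(n, ifelse(cls == "Tumor", 5, 1)),
      class = cls
    )
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    df
  })
}
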