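# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops over explicit sample index sets.

oracle_entropy <- function(l) {
  s <- 0
  for (cl in unique(l)) {
    p <- sum(l == cl) / length(l)
    s <- s - p * log2(p)
  }
  s
}

# gamma and positive region by exhaustive enumeration over all blocks of
# the P-partition and all decision classes.
oracle_gamma <- function(df, P, decision, alpha) {
  keyP <- do.call(paste, c(df[P], sep = "|"))
  keyD <- as.character(df[[decision]])
  pos <- character(0)
  for (kp in unique(keyP)) {
    y <- which(keyP == kp)
    ok <- FALSE
    for (kd in unique(keyD)) {
      x <- which(keyD == kd)
      if (length(intersect(y, x)) / length(y) >= alpha - 1e-12) ok <- TRUE
    }
    if (ok) pos <- c(pos, df$sample[y])
  }
  list(gamma = length(pos) / nrow(df), pos = sort(pos))
}

# All rules (antecedent value, consequent, confidence) by enumeration.
oracle_rules <- function(df, g, decision, alpha) {
  v <- as.character(df[[g]])
  d <- as.character(df[[decision]])
  out <- list()
  for (val in unique(v)) {
    y <- which(v == val)
    for (cl in unique(d)) {
      conf <- sum(d[y] == cl) / length(y)
      if (conf >= alpha - 1e-12) {
        out[[length(out) + 1]] <- data.frame(interval = val, consequent = cl,
                                             confidence = conf)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(interval = character(0), consequent = character(0),
                      confidence = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$interval, res$consequent), , drop = FALSE]
}

# Naive recursive MDL cut search: O(n^2) candidate scan with explicitly
# summed entropies; same acceptance criterion, independent code path.
oracle_mdlp <- function(v, l) {
  o <- order(v)
  v <- v[o]; l <- as.character(l[o])
  n <- length(v)
  if (length(unique(l)) < 2) return(numeric(0))
  dv <- sort(unique(v))
  cands <- numeric(0)
  for (i in seq_along(dv)[-1]) {
    s1 <- unique(l[v == dv[i - 1]]); s2 <- unique(l[v == dv[i]])
    if (!(length(s1) == 1 && length(s2) == 1 && s1 == s2)) {
      cands <- c(cands, (dv[i - 1] + dv[i]) / 2)
    }
  }
  if (length(cands) == 0) return(numeric(0))
  best <- NA_real_; best_gain <- -Inf
  for (ct in cands) {
    le <- l[v <= ct]; ri <- l[v > ct]
    gain <- oracle_entropy(l) -
      (length(le) * oracle_entropy(le) + length(ri) * oracle_entropy(ri)) / n
    if (gain > best_gain + 1e-12) {
      best_gain <- gain; best <- ct
    }
  }
  le <- l[v <= best]; ri <- l[v > best]
  k <- length(unique(l)); k1 <- length(unique(le)); k2 <- length(unique(ri))
  delta <- log2(3^k - 2) -
    (k * oracle_entropy(l) - k1 * oracle_entropy(le) - k2 * oracle_entropy(ri))
  if (best_gain <= log2(n - 1) / n + delta / n) return(numeric(0))
  sort(c(oracle_mdlp(v[v <= best], le), best, oracle_mdlp(v[v > best], ri)))
}
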