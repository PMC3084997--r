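# Independent brute-force oracles kept deliberately naive; they verify
# the package's faster implementations.

# pI by exhaustive scan of the charge curve on a fine pH grid
brute_pi <- function(sequence, by = 0.001) {
  tab <- pka_table()
  ch <- strsplit(sequence, "")[[1]]
  counts <- c(Nterm = 1, Cterm = 1)
  side <- table(ch[ch %in% tab$group])
  counts <- c(counts, stats::setNames(as.numeric(side), names(side)))
  grid <- seq(0, 14, by = by)
  q <- numeric(length(grid))
  for (g in names(counts)) {
    row <- tab[tab$group == g, ]
    contrib <- if (row$charge > 0) 1 / (1 + 10^(grid - row$pka)) else
      -1 / (1 + 10^(row$pka - grid))
    q <- q + counts[[g]] * contrib
  }
  grid[which.min(abs(q))]
}

# AROC as the fraction of concordant positive/negative pairs, ties half
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# MCC-maximizing cutoff by plain enumeration, independent of the sweep
brute_best_cutoff <- function(scores, labels) {
  best_mcc <- -Inf
  best_cut <- NA
  for (cut in sort(unique(scores))) {
    tp <- sum(scores >= cut & labels == 1)
    fp <- sum(scores >= cut & labels == 0)
    tn <- sum(scores < cut & labels == 0)
    fn <- sum(scores < cut & labels == 1)
    d <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    m <- if (d == 0) 0 else (tp * tn - fp * fn) / sqrt(d)
    if (m > best_mcc) {  # strict: earliest (smallest) cutoff wins ties
      best_mcc <- m
      best_cut <- cut
    }
  }
  list(cutoff = best_cut, mcc = best_mcc)
}

# single-linkage components by boolean transitive closure of the
# adjacency matrix
brute_components <- function(table, universe, threshold) {
  n <- length(universe)
  adj <- diag(TRUE, n)
  pass <- table[table$score >= threshold, , drop = FALSE]
  for (k in seq_len(nrow(pass))) {
    i <- match(pass$id_a[k], universe)
    j <- match(pass$id_b[k], universe)
    adj[i, j] <- adj[j, i] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  # canonical labels: smallest-id member of each row's component
  comp <- apply(adj, 1, function(row) min(universe[row]))
  stats::setNames(comp, universe)
}
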