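# Independent oracles used across tests. Each is a deliberately naive
# re-derivation of the property under test, kept separate from the package
# implementation.

# Expanded-observation Pearson correlation on a scored 2xC table: replicate
# each cell's (row score, column score) pair count-many times and call cor().
oracle_trend <- function(tab, col_scores, row_scores = c(0, 1)) {
  idx <- expand.grid(i = 1:2, j = seq_len(ncol(tab)))
  w <- tab[cbind(idx$i, idx$j)]
  x <- rep(row_scores[idx$i], w)
  y <- rep(col_scores[idx$j], w)
  n <- sum(tab)
  r <- stats::cor(x, y)
  list(r = r, M2 = (n - 1) * r^2, n = n)
}

# Gap clustering via explicit connected components of the gap graph.
oracle_cluster <- function(pos, max_gap) {
  upos <- sort(unique(pos))
  if (length(upos) == 0L) return(integer(0))
  comp <- seq_along(upos)
  for (i in seq_along(upos)[-1]) {
    if (upos[i] - upos[i - 1] <= max_gap) comp[i] <- comp[i - 1]
  }
  # map each original position to its component id
  comp[match(pos, upos)]
}

# Two-sided Fisher exact p by full enumeration of tables with fixed margins.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random non-degenerate scored 2xC table.
random_trend_table <- function(max_C = 6L, max_n = 500L) {
  repeat {
    C <- sample(2:max_C, 1L)
    n <- sample(4:max_n, 1L)
    tab <- matrix(stats::rmultinom(1L, n, rep(1, 2 * C)), nrow = 2L)
    scores <- sort(stats::runif(C))
    ok <- all(rowSums(tab) > 0) && sum(colSums(tab) > 0) >= 2L
    if (ok) return(list(tab = tab, scores = scores))
  }
}
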