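# Independent oracles and small fixture builders shared across the suite.

# Literal transcription of the printed ECI formula (numerator written as
# sign(b1 x -b2){max - (|b1| + |b2|)}), kept deliberately distinct from the
# simplified implementation it checks.
eci_literal <- function(b1, b2) {
  a1 <- abs(b1)
  a2 <- abs(b2)
  hi <- pmax(a1, a2)
  sign(b1 * -b2) * (hi - (a1 + a2)) / hi
}

# Brute-force two-sample KS statistic between in- and out-of-pathway ranks.
ks_oracle <- function(in_ranks, out_ranks) {
  grid <- sort(c(in_ranks, out_ranks))
  f1 <- vapply(grid, function(x) mean(in_ranks <= x), numeric(1))
  f2 <- vapply(grid, function(x) mean(out_ranks <= x), numeric(1))
  max(abs(f1 - f2))
}

# Exact hypergeometric upper-tail probability by direct summation of the
# counting formula: P(overlap >= k) for a pathway of size m drawn against a
# significant list of size n_sig in a universe of n_univ genes.
hyper_tail_oracle <- function(k, n_sig, n_univ, m) {
  i <- k:min(n_sig, m)
  sum(choose(n_sig, i) * choose(n_univ - n_sig, m - i)) / choose(n_univ, m)
}

# A ranked table with known statistics: `stat` values assigned to genes
# named in rank order (g01 highest).
ranked_fixture <- function(stat) {
  n <- length(stat)
  tibble::tibble(
    gene = sprintf("g%02d", seq_len(n)),
    weighted_eci = sort(stat, decreasing = TRUE),
    rank = seq_len(n)
  )
}

# Paired effect tables with a planted equivalently changed block of genes.
planted_pairs_fixture <- function(n_genes = 120, n_planted = 20, seed = 1) {
  set.seed(seed)
  pairs <- tibble::tibble(
    gene = sprintf("g%03d", seq_len(n_genes)),
    beta1 = rnorm(n_genes), beta2 = rnorm(n_genes),
    p1 = runif(n_genes), p2 = runif(n_genes)
  )
  idx <- seq_len(n_planted)
  pairs$beta2[idx] <- pairs$beta1[idx]
  pairs$p1[idx] <- pairs$p2[idx] <- 0.001
  list(pairs = pairs, planted = pairs$gene[idx])
}
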