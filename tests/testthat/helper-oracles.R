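# Independent oracles, kept deliberately naive and loop-based so they share
# no code path with the package implementation.

# KS tag statistic by explicit evaluation of the two running-difference
# sequences, one j at a time.
oracle_ks <- function(positions, n) {
  t <- length(positions)
  a <- -Inf; b <- -Inf
  for (j in seq_len(t)) {
    a <- max(a, j / t - positions[j] / n)
    b <- max(b, positions[j] / n - (j - 1) / t)
  }
  if (a >= b) a else -b
}

# Upper-tail hypergeometric probability by direct summation of
# combination counts.
oracle_hyper_tail <- function(k, n_draw, K, N) {
  ks <- seq.int(k, min(n_draw, K))
  sum(choose(K, ks) * choose(N - K, n_draw - ks)) / choose(N, n_draw)
}

# Tiny hand-built compendium: n probes x instances given as a list of rank
# vectors, molecules cycled over the instances.
tiny_compendium <- function(rank_cols, molecule_names) {
  n <- length(rank_cols[[1]])
  ranks <- do.call(cbind, rank_cols)
  rownames(ranks) <- paste0("g", seq_len(n))
  colnames(ranks) <- paste0("i", seq_along(rank_cols))
  meta <- data.frame(instance_id = colnames(ranks),
                     molecule_name = rep_len(molecule_names, ncol(ranks)),
                     cell_line = "CL1", dose = "1uM", batch = "b1",
                     stringsAsFactors = FALSE)
  rank_compendium(ranks, meta)
}

# All non-empty subsets of 1..n as a list of sorted integer vectors.
all_subsets <- function(n) {
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    out[[mask]] <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0L)
  }
  out
}
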