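# Small generator configurations and deterministic fixtures used across
# test files.

small_sim <- function(seed = 1, n_bits = 120) {
  generate_fingerprint_dataset(generator_config(
    n_compounds = 60, n_potent = 45, n_bits = n_bits,
    enriched = data.frame(bit_name = c("E1", "E2"),
                          p_P = c(0.6, 0.4), p_N = c(0.1, 0.05)),
    background_p = 0.3, n_constant_bits = 4, n_correlated_pairs = 4,
    seed = seed))
}

# Binary matrix with exactly the requested per-class presence counts for
# one planted bit, plus `extra` filler bits.
planted_count_matrix <- function(n_P, n_N, with_P, with_N, extra = 2) {
  n <- n_P + n_N
  labels <- rep(c("P", "N"), c(n_P, n_N))
  planted <- c(rep(1, with_P), rep(0, n_P - with_P),
               rep(1, with_N), rep(0, n_N - with_N))
  fp <- cbind(planted, matrix(rep(c(0, 1), length.out = n * extra), n, extra))
  colnames(fp) <- c("planted", sprintf("filler%d", seq_len(extra)))
  rownames(fp) <- sprintf("c%03d", seq_len(n))
  list(fp = fp, labels = labels)
}

# Exhaustive O(n^2) scan for mutual cross-class nearest-neighbor pairs,
# same tie-break (lowest index wins) as the implementation.
brute_force_tomek <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  nn <- vapply(seq_len(n), function(i) {
    cand <- which(d[i, ] == min(d[i, ]))
    min(cand)
  }, integer(1))
  pairs <- list()
  for (a in seq_len(n)) {
    b <- nn[a]
    if (a < b && nn[b] == a && labels[a] != labels[b])
      pairs[[length(pairs) + 1L]] <- c(a, b)
  }
  if (length(pairs) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, pairs)
}
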