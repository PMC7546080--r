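# Brute-force oracles, kept independent of the package internals they
# check.

# Every equally likely value of V = sum w_i R_i when the m set genes'
# ranks are a uniform injection into {1..n}: enumerate all ordered
# m-tuples of distinct ranks. Only feasible for tiny n^m.
oracleNullValues <- function(w, n) {
  m <- length(w)
  g <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), m)))
  keep <- apply(g, 1, function(r) anyDuplicated(r) == 0L)
  as.vector(g[keep, , drop = FALSE] %*% w)
}

oracleTailProb <- function(w, n, v) {
  vals <- oracleNullValues(w, n)
  mean(vals <= v + 1e-9)
}

# Hypergeometric upper tail by exhaustive enumeration of all m-subsets of
# an n-gene background with K significant genes.
oracleOverrepTail <- function(n, K, m, x) {
  sets <- combn(n, m)
  hits <- colSums(sets <= K)   # genes 1..K are the significant ones
  mean(hits >= x)
}

# A small ranked background with deterministic p-values.
makeRanked <- function(n) {
  rankGenes(sprintf("g%04d", seq_len(n)), seq(0.001, 0.999, length.out = n))
}
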