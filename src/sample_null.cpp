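#include <Rcpp.h>
using namespace Rcpp;

// K Monte-Carlo draws of V = sum_j w_j R_j where (R_1..R_m) is a uniformly
// random injection from the set genes into the ranks {1..n} (sampling
// without replacement). Partial Fisher-Yates over a persistent pool with an
// O(m) undo per draw, so each draw costs O(m) regardless of n. Uses R's RNG
// so results are reproducible from set.seed().
// [[Rcpp::export]]
NumericVector cpp_sample_null(NumericVector w, int n, double K) {
  const int m = w.size();
  if (m > n) stop("set size m exceeds background size n");
  const R_xlen_t KK = (R_xlen_t) K;
  NumericVector out((R_xlen_t) KK);
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i + 1;
  std::vector<int> picks(m);
  GetRNGstate();
  for (R_xlen_t s = 0; s < KK; ++s) {
    double v = 0.0;
    for (int j = 0; j < m; ++j) {
      int r = j + (int) R_unif_index(n - j);
      picks[j] = r;
      std::swap(pool[j], pool[r]);
      v += w[j] * pool[j];
    }
    for (int j = m - 1; j >= 0; --j) std::swap(pool[j], pool[picks[j]]);
    out[s] = v;
  }
  PutRNGstate();
  return out;
}

// Column-wise ranks of a matrix (no ties expected: continuous input).
// Used by the correlated-latent-rank sampler.
// [[Rcpp::export]]
IntegerMatrix cpp_col_ranks(NumericMatrix x) {
  const int n = x.nrow(), K = x.ncol();
  IntegerMatrix out(n, K);
  std::vector<int> idx(n);
  for (int c = 0; c < K; ++c) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    NumericMatrix::Column col = x(_, c);
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    for (int i = 0; i < n; ++i) out(idx[i], c) = i + 1;
  }
  return out;
}
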