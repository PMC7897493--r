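#include <Rcpp.h>
using namespace Rcpp;

// Sample a discrete-time Markov chain of length n_steps from row-stochastic
// cumulative matrix `cum` (k x k, rows are cumulative sums ending at 1).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(NumericMatrix cum, int n_steps, int start) {
  int k = cum.nrow();
  IntegerVector out(n_steps);
  int s = start - 1; // 0-based
  out[0] = s + 1;
  for (int t = 1; t < n_steps; ++t) {
    double u = unif_rand();
    // binary search in row s
    int lo = 0, hi = k - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cum(s, mid) < u) lo = mid + 1; else hi = mid;
    }
    s = lo;
    out[t] = s + 1;
  }
  return out;
}

// Transition counts at a given lag with sliding-window counting, 1-based
// labels, no counting across trajectory boundaries (caller passes one
// trajectory at a time is avoided by offsets).
// [[Rcpp::export]]
NumericMatrix count_pairs_cpp(IntegerVector labels, IntegerVector traj_len,
                              int lag, int n_states) {
  NumericMatrix C(n_states, n_states);
  int off = 0;
  for (int j = 0; j < traj_len.size(); ++j) {
    int L = traj_len[j];
    for (int t = 0; t + lag < L; ++t) {
      int a = labels[off + t] - 1;
      int b = labels[off + t + lag] - 1;
      C(a, b) += 1.0;
    }
    off += L;
  }
  return C;
}
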