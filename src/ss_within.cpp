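#include <Rcpp.h>
using namespace Rcpp;

// Within-group sum of squares for an assignment vector over a symmetric
// dissimilarity matrix whose entries are consumed as squared distances:
//   SS(WP) = sum_g (1 / (2 n_g)) * sum_{i,j in g} m_ij
// assign is 1-based with values in 1..K; empty clusters contribute 0.
// [[Rcpp::export]]
double ss_within_cpp(NumericMatrix m, IntegerVector assign, int K) {
  int n = m.nrow();
  std::vector<double> acc(K, 0.0);
  std::vector<int> cnt(K, 0);
  for (int i = 0; i < n; ++i) cnt[assign[i] - 1]++;
  for (int i = 0; i < n; ++i) {
    int gi = assign[i] - 1;
    for (int j = i + 1; j < n; ++j) {
      if (assign[j] - 1 == gi) acc[gi] += m(j, i);
    }
  }
  double ss = 0.0;
  for (int g = 0; g < K; ++g) {
    if (cnt[g] > 0) ss += acc[g] / cnt[g];  // off-diagonal pairs counted once = sum/2 * 2
  }
  return ss;
}
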