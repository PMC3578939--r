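#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// k-nearest-neighbour voting for several k at once. D is the test-by-train
// distance matrix, y the 1-based training labels. Neighbours are taken in
// stable order of increasing distance; among classes tied for the most votes
// the class of the nearest neighbour belonging to a tied class wins.
// [[Rcpp::export]]
IntegerMatrix knn_vote_cpp(NumericMatrix D, IntegerVector y,
                           IntegerVector ks, int n_classes) {
  const int n = D.nrow(), m = D.ncol(), nk = ks.size();
  IntegerMatrix out(n, nk);
  std::vector<int> idx(m);
  std::vector<double> dr(m);
  std::vector<int> votes(n_classes);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) { idx[j] = j; dr[j] = D(i, j); }
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return dr[a] < dr[b]; });
    for (int q = 0; q < nk; ++q) {
      const int k = std::min<int>(ks[q], m);
      std::fill(votes.begin(), votes.end(), 0);
      for (int j = 0; j < k; ++j) votes[y[idx[j]] - 1]++;
      const int best = *std::max_element(votes.begin(), votes.end());
      int ntied = 0, pred = 0;
      for (int c = 0; c < n_classes; ++c) if (votes[c] == best) { ++ntied; if (!pred) pred = c + 1; }
      if (ntied > 1) {
        for (int j = 0; j < k; ++j) {
          const int c = y[idx[j]];
          if (votes[c - 1] == best) { pred = c; break; }
        }
      }
      out(i, q) = pred;
    }
  }
  return out;
}
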