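// Greedy incremental redundancy clustering of equal-length fragments.
// Fragments are processed in input order; a fragment joins the first cluster
// whose representative shares >= threshold identity, else founds a new
// cluster. Identity = exact matching columns / total columns; the pad symbol
// (code `pad_code`) never counts as a match, even against itself.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List greedy_cluster_cpp(IntegerMatrix codes, double threshold, int pad_code) {
  int n = codes.nrow(), L = codes.ncol();
  std::vector<int> reps;          // row indices of representatives
  IntegerVector cluster(n);
  int need = (int)std::ceil(threshold * L - 1e-9);
  for (int i = 0; i < n; ++i) {
    int assigned = -1;
    for (size_t r = 0; r < reps.size(); ++r) {
      int rep = reps[r], match = 0;
      for (int j = 0; j < L; ++j) {
        int a = codes(i, j);
        if (a == codes(rep, j) && a != pad_code) ++match;
        if (match + (L - 1 - j) < need) break;  // cannot reach threshold
      }
      if (match >= need) { assigned = (int)r; break; }
    }
    if (assigned < 0) { reps.push_back(i); assigned = (int)reps.size() - 1; }
    cluster[i] = assigned + 1;
  }
  IntegerVector rep_idx(reps.size());
  for (size_t r = 0; r < reps.size(); ++r) rep_idx[r] = reps[r] + 1;
  return List::create(_["representatives"] = rep_idx, _["cluster"] = cluster);
}
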