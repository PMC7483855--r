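#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Disjoint-set union over n items (1-based) given a two-column matrix of
// merge pairs. Returns, for every item, the smallest item id in its
// component, so the labelling is independent of merge order.
// [[Rcpp::export(name = ".union_find")]]
IntegerVector union_find(int n, IntegerMatrix merges) {
  std::vector<int> parent(n), rank_(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;
  struct F {
    static int find(std::vector<int>& p, int x) {
      while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
      return x;
    }
  };
  int nm = merges.nrow();
  for (int t = 0; t < nm; ++t) {
    int x = F::find(parent, merges(t, 0) - 1);
    int y = F::find(parent, merges(t, 1) - 1);
    if (x == y) continue;
    if (rank_[x] < rank_[y]) std::swap(x, y);
    parent[y] = x;
    if (rank_[x] == rank_[y]) ++rank_[x];
  }
  std::vector<int> label(n, 0);
  for (int i = 0; i < n; ++i) {
    int r = F::find(parent, i);
    if (label[r] == 0) label[r] = i + 1;  // first-seen = smallest index
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = label[F::find(parent, i)];
  return out;
}
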