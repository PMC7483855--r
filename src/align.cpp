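#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Optimal chain of matching marker occurrences between two marker id
// sequences, subject to banding constraints:
//   - per-read skip between consecutive aligned markers <= max_skip
//   - unaligned markers at each end <= max_trim on at least one read
// Objective: maximise aligned count; ties by smaller total skip, then by
// lexicographically earliest chain of (i, j) pairs.
// DP runs right-to-left over match cells so the traceback from the best
// start cell is greedy-lexicographic.
// [[Rcpp::export(name = ".chain_align")]]
List chain_align(IntegerVector a, IntegerVector b, int max_skip, int max_trim) {
  int na = a.size(), nb = b.size();
  std::unordered_map<int, std::vector<int> > posb;
  for (int j = 0; j < nb; ++j) posb[b[j]].push_back(j);
  std::vector<int> ci, cj;
  for (int i = 0; i < na; ++i) {
    std::unordered_map<int, std::vector<int> >::iterator it = posb.find(a[i]);
    if (it == posb.end()) continue;
    for (size_t t = 0; t < it->second.size(); ++t) {
      ci.push_back(i);
      cj.push_back(it->second[t]);
    }
  }
  int M = (int) ci.size();
  if (M == 0)
    return List::create(_["count"] = 0, _["skip"] = 0,
                        _["pairs"] = IntegerMatrix(0, 2));
  // cells are already sorted by (i, j) because a is scanned in order and
  // positions in b are ascending
  // index of first cell with given i
  std::vector<int> row_start(na + 1, M);
  for (int c = M - 1; c >= 0; --c) row_start[ci[c]] = c;
  for (int i = na - 1; i >= 0; --i)
    if (row_start[i] == M) row_start[i] = row_start[i + 1];

  std::vector<int> cnt(M, 0), skp(M, 0), nxt(M, -1);
  for (int c = M - 1; c >= 0; --c) {
    int i = ci[c], j = cj[c];
    int bc = -1, bs = 0, bn = -1;
    // end the chain here if trims admissible: on each side, the
    // alignment must come within max_trim of the end of at least one
    // read (dovetail overlaps leave the other read's tail unaligned)
    if (std::min(na - 1 - i, nb - 1 - j) <= max_trim) {
      bc = 1; bs = 0; bn = -1;
    }
    int imax = i + max_skip + 1;
    if (imax > na - 1) imax = na - 1;
    for (int d = row_start[i + 1]; d < M && ci[d] <= imax; ++d) {
      if (cnt[d] <= 0) continue;
      int dj = cj[d] - j - 1;
      if (dj < 0 || dj > max_skip) continue;
      int ncand = cnt[d] + 1;
      int scand = skp[d] + (ci[d] - i - 1) + dj;
      if (ncand > bc || (ncand == bc && scand < bs)) {
        bc = ncand; bs = scand; bn = d;
      }
      // equal (count, skip): keep earlier (smaller (i, j)) successor,
      // which is the one already held since cells are scanned in order
    }
    cnt[c] = bc; skp[c] = bs; nxt[c] = bn;
  }
  int best = -1;
  for (int c = 0; c < M; ++c) {
    if (cnt[c] <= 0) continue;
    if (std::min(ci[c], cj[c]) > max_trim) continue;
    if (best < 0 || cnt[c] > cnt[best] ||
        (cnt[c] == cnt[best] && skp[c] < skp[best]))
      best = c;
    // ties keep the earlier cell: scan order is (i, j) ascending
  }
  if (best < 0)
    return List::create(_["count"] = 0, _["skip"] = 0,
                        _["pairs"] = IntegerMatrix(0, 2));
  int n = cnt[best];
  IntegerMatrix pairs(n, 2);
  int c = best;
  for (int t = 0; t < n; ++t) {
    pairs(t, 0) = ci[c] + 1;  // 1-based ordinals for R
    pairs(t, 1) = cj[c] + 1;
    c = nxt[c];
  }
  return List::create(_["count"] = n, _["skip"] = skp[best],
                      _["pairs"] = pairs);
}

// Global banded edit distance (unit costs) between strings a and b.
// The band is centred on the rescaled diagonal. Returns -1 if the band
// is pinched shut.
// [[Rcpp::export(name = ".banded_edit_distance")]]
double banded_edit_distance(std::string a, std::string b, int band) {
  int n = (int) a.size(), m = (int) b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  double slope = (double) m / (double) n;
  const int BIG = 1 << 28;
  std::vector<int> prev, cur;
  int plo = 0, phi = std::min(m, band);  // row 0 columns
  prev.assign(phi - plo + 1, 0);
  for (int j = plo; j <= phi; ++j) prev[j - plo] = j;
  for (int i = 1; i <= n; ++i) {
    int cen = (int) (i * slope + 0.5);
    int lo = std::max(0, cen - band), hi = std::min(m, cen + band);
    cur.assign(hi - lo + 1, BIG);
    for (int j = lo; j <= hi; ++j) {
      int best = BIG;
      if (j == 0) best = i;
      if (j > lo) best = std::min(best, cur[j - 1 - lo] + 1);
      if (j >= plo && j <= phi) best = std::min(best, prev[j - plo] + 1);
      if (j - 1 >= plo && j - 1 <= phi && j >= 1) {
        int d = prev[j - 1 - plo] + (a[i - 1] == b[j - 1] ? 0 : 1);
        best = std::min(best, d);
      }
      cur[j - lo] = best;
    }
    prev.swap(cur); plo = lo; phi = hi;
  }
  if (m < plo || m > phi || prev[m - plo] >= BIG) return -1.0;
  return (double) prev[m - plo];
}

// Fitting alignment distance: all of a against some substring of b
// (free end gaps in b). Banded as above. Returns -1 on band failure.
// [[Rcpp::export(name = ".banded_fit_distance")]]
double banded_fit_distance(std::string a, std::string b, int band) {
  int n = (int) a.size(), m = (int) b.size();
  if (n == 0) return 0;
  if (m == 0) return n;
  double slope = (double) m / (double) n;
  const int BIG = 1 << 28;
  std::vector<int> prev, cur;
  int plo = 0, phi = m;
  prev.assign(m + 1, 0);          // free start anywhere in b
  for (int i = 1; i <= n; ++i) {
    int cen = (int) (i * slope + 0.5);
    int lo = std::max(0, cen - band), hi = std::min(m, cen + band);
    cur.assign(hi - lo + 1, BIG);
    for (int j = lo; j <= hi; ++j) {
      int best = BIG;
      if (j == 0) best = i;
      if (j > lo) best = std::min(best, cur[j - 1 - lo] + 1);
      if (j >= plo && j <= phi) best = std::min(best, prev[j - plo] + 1);
      if (j - 1 >= plo && j - 1 <= phi && j >= 1)
        best = std::min(best, prev[j - 1 - plo] +
                                  (a[i - 1] == b[j - 1] ? 0 : 1));
      cur[j - lo] = best;
    }
    prev.swap(cur); plo = lo; phi = hi;
  }
  int bestd = BIG;
  for (size_t t = 0; t < prev.size(); ++t) bestd = std::min(bestd, prev[t]);
  if (bestd >= BIG) return -1.0;
  return (double) bestd;           // free end anywhere in b
}
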