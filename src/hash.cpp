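#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// splitmix64: well-mixed 64-bit hash, platform-stable
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

//' @noRd
// [[Rcpp::export(name = ".feature_hashes")]]
NumericVector feature_hashes(IntegerVector ids, int m, double salt) {
  int n = ids.size();
  int nf = n - m + 1;
  if (nf < 1 || m < 1) return NumericVector(0);
  NumericVector out(nf);
  uint64_t s = splitmix64((uint64_t) salt);
  for (int i = 0; i < nf; ++i) {
    uint64_t h = s;
    for (int j = 0; j < m; ++j)
      h = splitmix64(h ^ (uint64_t)(uint32_t) ids[i + j]);
    // top 53 bits -> double in [0,1)
    out[i] = (double)(h >> 11) * (1.0 / 9007199254740992.0);
  }
  return out;
}

// rolling codes of k-mers over the 4-letter alphabet; b holds 0..3
// [[Rcpp::export(name = ".kmer_codes")]]
NumericVector kmer_codes(IntegerVector b, int k) {
  int n = b.size();
  int nw = n - k + 1;
  if (nw < 1) return NumericVector(0);
  NumericVector out(nw);
  double top = 1.0;
  for (int i = 0; i < k - 1; ++i) top *= 4.0;
  double code = 0.0;
  for (int j = 0; j < k; ++j) code = code * 4.0 + b[j];
  out[0] = code;
  for (int i = 1; i < nw; ++i) {
    code = (code - b[i - 1] * top) * 4.0 + b[i + k - 1];
    out[i] = code;
  }
  return out;
}
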