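#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Three-state (match / read-insertion / assembly-deletion) affine-gap
// pair-HMM, conditional on the assembly sequence: forward log-likelihood
// P(read | assembly) and banded forward-backward posterior probabilities.
// Sequences are passed as integer vectors over 0..3 (A,C,G,T).

namespace {
const double NEG_INF = -1e300;

inline double lse2(double a, double b) {
  if (a < b) std::swap(a, b);
  if (b <= NEG_INF / 2) return a;
  return a + log1p(std::exp(b - a));
}
inline double lse3(double a, double b, double c) { return lse2(lse2(a, b), c); }

struct Hmm {
  double t[3][3];   // log transitions, states 0=M 1=X(ins) 2=Y(del)
  double lm_eq, lm_ne, lq;
  Hmm(NumericVector trans, double pm_eq, double qins) {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        t[i][j] = trans[3 * i + j] > 0 ? std::log(trans[3 * i + j]) : NEG_INF;
    lm_eq = std::log(pm_eq);
    lm_ne = std::log((1.0 - pm_eq) / 3.0);
    lq = std::log(qins);
  }
  inline double em(int rb, int sb) const { return rb == sb ? lm_eq : lm_ne; }
};
}

// [[Rcpp::export(name = ".forward_loglik")]]
double forward_loglik(IntegerVector r, IntegerVector s, NumericVector trans,
                      double pm_eq, double qins) {
  Hmm h(trans, pm_eq, qins);
  int m = r.size(), n = s.size();
  std::vector<double> M((m + 1) * (n + 1), NEG_INF), X = M, Y = M;
  int w = n + 1;
  M[0] = 0.0;
  for (int i = 0; i <= m; ++i) {
    for (int j = 0; j <= n; ++j) {
      int c = i * w + j;
      if (i > 0 && j > 0)
        M[c] = h.em(r[i - 1], s[j - 1]) +
               lse3(M[c - w - 1] + h.t[0][0], X[c - w - 1] + h.t[1][0],
                    Y[c - w - 1] + h.t[2][0]);
      if (i > 0)
        X[c] = h.lq + lse3(M[c - w] + h.t[0][1], X[c - w] + h.t[1][1],
                           Y[c - w] + h.t[2][1]);
      if (j > 0)
        Y[c] = lse3(M[c - 1] + h.t[0][2], X[c - 1] + h.t[1][2],
                    Y[c - 1] + h.t[2][2]);
    }
  }
  int c = m * w + n;
  return lse3(M[c], X[c], Y[c]);
}

// Banded forward-backward. lo/hi give, for each read row i in 0..m, the
// admissible assembly coordinate range (0-based, inclusive). Returns
// sparse posterior triplets (1-based coordinates) at or above `threshold`
// plus the total log-likelihood.
//   match: P(r_i diamond s_j)
//   ins:   P(r_i diamond -j)   read base i inserted after assembly base j
//   del:   P(-i diamond s_j)   assembly base j deleted after read base i
// Deletions at read boundaries (i == 0 or i == m) are not reported.
// [[Rcpp::export(name = ".fb_posteriors")]]
List fb_posteriors(IntegerVector r, IntegerVector s, NumericVector trans,
                   double pm_eq, double qins, IntegerVector lo,
                   IntegerVector hi, double threshold) {
  Hmm h(trans, pm_eq, qins);
  int m = r.size(), n = s.size();
  std::vector<int> L(m + 1), H(m + 1), off(m + 2, 0);
  for (int i = 0; i <= m; ++i) {
    L[i] = std::max(0, std::min(lo[i], n));
    H[i] = std::max(L[i], std::min(hi[i], n));
    off[i + 1] = off[i] + (H[i] - L[i] + 1);
  }
  // force corners into the band
  if (L[0] > 0) { L[0] = 0; }
  if (H[m] < n) { H[m] = n; }
  off[0] = 0;
  for (int i = 0; i <= m; ++i) off[i + 1] = off[i] + (H[i] - L[i] + 1);
  int tot = off[m + 1];
  std::vector<double> fM(tot, NEG_INF), fX(tot, NEG_INF), fY(tot, NEG_INF);
  std::vector<double> bM(tot, NEG_INF), bX(tot, NEG_INF), bY(tot, NEG_INF);
  #define IN(i, j) ((j) >= L[(i)] && (j) <= H[(i)])
  #define IX(i, j) (off[(i)] + (j) - L[(i)])
  fM[IX(0, 0)] = 0.0;
  for (int i = 0; i <= m; ++i) {
    for (int j = L[i]; j <= H[i]; ++j) {
      int c = IX(i, j);
      if (i > 0 && j > 0 && IN(i - 1, j - 1)) {
        int p = IX(i - 1, j - 1);
        fM[c] = h.em(r[i - 1], s[j - 1]) +
                lse3(fM[p] + h.t[0][0], fX[p] + h.t[1][0], fY[p] + h.t[2][0]);
      }
      if (i > 0 && IN(i - 1, j)) {
        int p = IX(i - 1, j);
        fX[c] = h.lq +
                lse3(fM[p] + h.t[0][1], fX[p] + h.t[1][1], fY[p] + h.t[2][1]);
      }
      if (j > 0 && IN(i, j - 1)) {
        int p = IX(i, j - 1);
        fY[c] = lse3(fM[p] + h.t[0][2], fX[p] + h.t[1][2], fY[p] + h.t[2][2]);
      }
    }
  }
  int cend = IX(m, n);
  double total = lse3(fM[cend], fX[cend], fY[cend]);
  bM[cend] = bX[cend] = bY[cend] = 0.0;
  for (int i = m; i >= 0; --i) {
    for (int j = H[i]; j >= L[i]; --j) {
      int c = IX(i, j);
      if (i == m && j == n) continue;
      double vm = NEG_INF, vx = NEG_INF, vy = NEG_INF;
      if (i < m && j < n && IN(i + 1, j + 1)) {
        int q = IX(i + 1, j + 1);
        double e = h.em(r[i], s[j]) + bM[q];
        vm = lse2(vm, h.t[0][0] + e);
        vx = lse2(vx, h.t[1][0] + e);
        vy = lse2(vy, h.t[2][0] + e);
      }
      if (i < m && IN(i + 1, j)) {
        int q = IX(i + 1, j);
        double e = h.lq + bX[q];
        vm = lse2(vm, h.t[0][1] + e);
        vx = lse2(vx, h.t[1][1] + e);
        vy = lse2(vy, h.t[2][1] + e);
      }
      if (j < n && IN(i, j + 1)) {
        int q = IX(i, j + 1);
        double e = bY[q];
        vm = lse2(vm, h.t[0][2] + e);
        vx = lse2(vx, h.t[1][2] + e);
        vy = lse2(vy, h.t[2][2] + e);
      }
      bM[c] = vm; bX[c] = vx; bY[c] = vy;
    }
  }
  std::vector<int> mi, mj, xi, xj, yi, yj;
  std::vector<double> mp, xp, yp;
  double lth = std::log(threshold);
  for (int i = 0; i <= m; ++i) {
    for (int j = L[i]; j <= H[i]; ++j) {
      int c = IX(i, j);
      if (i > 0 && j > 0 && fM[c] + bM[c] - total >= lth) {
        mi.push_back(i); mj.push_back(j);
        mp.push_back(std::exp(fM[c] + bM[c] - total));
      }
      if (i > 0 && fX[c] + bX[c] - total >= lth) {
        xi.push_back(i); xj.push_back(j);
        xp.push_back(std::exp(fX[c] + bX[c] - total));
      }
      if (j > 0 && i > 0 && i < m && fY[c] + bY[c] - total >= lth) {
        yi.push_back(i); yj.push_back(j);
        yp.push_back(std::exp(fY[c] + bY[c] - total));
      }
    }
  }
  #undef IN
  #undef IX
  return List::create(
      _["match"] = DataFrame::create(_["i"] = mi, _["j"] = mj, _["p"] = mp),
      _["ins"] = DataFrame::create(_["i"] = xi, _["j"] = xj, _["p"] = xp),
      _["del"] = DataFrame::create(_["i"] = yi, _["j"] = yj, _["p"] = yp),
      _["loglik"] = total);
}
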