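#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Progressive profile multiple alignment of short sequences, globally
// anchored at both ends, with column-majority consensus. Returns the
// consensus string and, for each input sequence, the 1-based source
// position contributing to each consensus column (0 = gap).
// Ties in a column: non-gap beats gap, then alphabetically smallest base.
namespace {
struct Column {
  int cnt[5];                 // A C G T gap
  std::vector<int> pos;       // per processed sequence: 1-based pos or 0
  Column() { cnt[0] = cnt[1] = cnt[2] = cnt[3] = cnt[4] = 0; }
};
inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; }
  return -1;
}
}

// [[Rcpp::export(name = ".msa_consensus")]]
List msa_consensus_cpp(CharacterVector seqs, double match, double mismatch,
                       double gap) {
  int ns = seqs.size();
  std::vector<Column> cols;
  int nproc = 0;
  for (int si = 0; si < ns; ++si) {
    std::string s = as<std::string>(seqs[si]);
    int m = (int) s.size();
    std::vector<int> sc(m);
    for (int i = 0; i < m; ++i) sc[i] = base_code(s[i]);
    int nc = (int) cols.size();
    if (nproc == 0) {
      for (int i = 0; i < m; ++i) {
        Column c;
        c.cnt[sc[i]]++;
        c.pos.push_back(i + 1);
        cols.push_back(c);
      }
      nproc = 1;
      continue;
    }
    // profile scores
    std::vector<double> colgap(nc);          // score of column vs gap in seq
    std::vector<std::vector<double> > colchr(nc, std::vector<double>(4));
    for (int c = 0; c < nc; ++c) {
      int nb = cols[c].cnt[0] + cols[c].cnt[1] + cols[c].cnt[2] + cols[c].cnt[3];
      colgap[c] = nb * gap;
      for (int x = 0; x < 4; ++x)
        colchr[c][x] = (nb - cols[c].cnt[x]) * mismatch +
                       cols[c].cnt[x] * match + cols[c].cnt[4] * gap;
    }
    double newcol = nproc * gap;             // char vs all-gap new column
    // global DP over (profile column, seq position)
    std::vector<std::vector<double> > S(nc + 1, std::vector<double>(m + 1));
    std::vector<std::vector<char> > T(nc + 1, std::vector<char>(m + 1));
    S[0][0] = 0;
    for (int j = 1; j <= m; ++j) { S[0][j] = S[0][j - 1] + newcol; T[0][j] = 'I'; }
    for (int c = 1; c <= nc; ++c) { S[c][0] = S[c - 1][0] + colgap[c - 1]; T[c][0] = 'D'; }
    for (int c = 1; c <= nc; ++c) {
      for (int j = 1; j <= m; ++j) {
        double dM = S[c - 1][j - 1] + colchr[c - 1][sc[j - 1]];
        double dD = S[c - 1][j] + colgap[c - 1];
        double dI = S[c][j - 1] + newcol;
        if (dM >= dD && dM >= dI)      { S[c][j] = dM; T[c][j] = 'M'; }
        else if (dD >= dI)             { S[c][j] = dD; T[c][j] = 'D'; }
        else                           { S[c][j] = dI; T[c][j] = 'I'; }
      }
    }
    // traceback, building the merged column list
    std::vector<Column> merged;
    int c = nc, j = m;
    while (c > 0 || j > 0) {
      char op = (c == 0) ? 'I' : (j == 0 ? 'D' : T[c][j]);
      if (op == 'M') {
        Column col = cols[c - 1];
        col.cnt[sc[j - 1]]++;
        col.pos.push_back(j);
        merged.push_back(col);
        --c; --j;
      } else if (op == 'D') {
        Column col = cols[c - 1];
        col.cnt[4]++;
        col.pos.push_back(0);
        merged.push_back(col);
        --c;
      } else {
        Column col;
        col.cnt[4] = nproc;
        col.pos.assign(nproc, 0);
        col.cnt[sc[j - 1]]++;
        col.pos.push_back(j);
        merged.push_back(col);
        --j;
      }
    }
    std::reverse(merged.begin(), merged.end());
    cols.swap(merged);
    ++nproc;
  }
  // consensus
  std::string cons;
  std::vector<int> keep;
  const char* alpha = "ACGT";
  for (size_t c = 0; c < cols.size(); ++c) {
    int bi = 0;
    for (int x = 1; x < 4; ++x) if (cols[c].cnt[x] > cols[c].cnt[bi]) bi = x;
    if (cols[c].cnt[4] > cols[c].cnt[bi]) continue;   // gap wins strictly
    cons.push_back(alpha[bi]);
    keep.push_back((int) c);
  }
  IntegerMatrix map((int) seqs.size(), (int) keep.size());
  for (size_t t = 0; t < keep.size(); ++t)
    for (int s = 0; s < ns; ++s)
      map(s, (int) t) = cols[keep[t]].pos[s];
  return List::create(_["consensus"] = cons, _["map"] = map);
}
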