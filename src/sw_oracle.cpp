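#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Exhaustive full-matrix Smith-Waterman local aligner (affine gaps), used as
// an independent reference against the seed-and-extend implementation. It
// enumerates every DP cell, so it is exact but quadratic; intended for
// sequences up to a few kb.
//
// `triangle = true` restricts to the strictly upper triangle (every aligned
// pair has query position < subject position), which is how a sequence is
// compared against itself on the same strand without the trivial main
// diagonal.

namespace {

inline int ocode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return 4;
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_sw_local")]]
List cpp_sw_local(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_extend, bool triangle) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<int> A(n), B(m);
  for (int i = 0; i < n; ++i) A[i] = ocode(a[i]);
  for (int j = 0; j < m; ++j) B[j] = ocode(b[j]);

  const int INEG = -1000000000;
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, INEG), Ecur(m + 1, INEG); // gap in query
  std::vector<int> Fprev(m + 1, INEG), Fcur(m + 1, INEG); // gap in subject
  // traceback: 0 stop, 1 diag(M), 2 from E, 3 from F (for H)
  // for E: bit 0 = extended; for F likewise
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbF((size_t)(n + 1) * (m + 1), 0);
  auto at = [&](int i, int j) { return (size_t)i * (m + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0; Ecur[0] = INEG; Fcur[0] = INEG;
    for (int j = 1; j <= m; ++j) {
      if (triangle && (i - 1) >= (j - 1)) { // aligned pair on/below diagonal
        Hcur[j] = 0; Ecur[j] = INEG; Fcur[j] = INEG;
        continue;
      }
      // E: gap in query (move along subject)
      int eo = Hcur[j - 1] - gap_open - gap_extend;
      int ee = (Ecur[j - 1] != INEG) ? Ecur[j - 1] - gap_extend : INEG;
      if (eo >= ee) { Ecur[j] = eo; tbE[at(i, j)] = 0; }
      else { Ecur[j] = ee; tbE[at(i, j)] = 1; }
      // F: gap in subject (move along query)
      int fo = Hprev[j] - gap_open - gap_extend;
      int fe = (Fprev[j] != INEG) ? Fprev[j] - gap_extend : INEG;
      if (fo >= fe) { Fcur[j] = fo; tbF[at(i, j)] = 0; }
      else { Fcur[j] = fe; tbF[at(i, j)] = 1; }
      int sc = (A[i - 1] < 4 && A[i - 1] == B[j - 1]) ? match : mismatch;
      int diag = Hprev[j - 1] + sc;
      int h = 0; uint8_t t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; t = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; t = 3; }
      Hcur[j] = h; tbH[at(i, j)] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  if (best <= 0) {
    return List::create(_["score"] = 0);
  }
  // traceback from (bi, bj), state H
  int i = bi, j = bj, state = 0; // 0=H, 1=E, 2=F
  int matches = 0, columns = 0;
  int qe = bi, se = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      uint8_t t = tbH[at(i, j)];
      if (t == 0) break;
      if (t == 1) {
        ++columns;
        if (A[i - 1] < 4 && A[i - 1] == B[j - 1]) ++matches;
        --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // E: gap in query, consumed subject base
      ++columns;
      uint8_t t = tbE[at(i, j)];
      --j;
      state = (t == 0) ? 0 : 1;
    } else { // F: gap in subject, consumed query base
      ++columns;
      uint8_t t = tbF[at(i, j)];
      --i;
      state = (t == 0) ? 0 : 2;
    }
  }
  int qb = i, sb = j;
  return List::create(
      _["score"] = best, _["q_start"] = qb, _["q_end"] = qe,
      _["s_start"] = sb, _["s_end"] = se, _["matches"] = matches,
      _["aln_length"] = columns);
}
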