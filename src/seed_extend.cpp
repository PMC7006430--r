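#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend local self-aligner.
//
// Finds local alignments of a nucleotide sequence against itself on both
// strand relations: "same" (plus/plus, tandem duplications) and "opposite"
// (plus/minus, inverted duplications, i.e. putative dsRNA stems).
//
// Pipeline per strand relation:
//   1. exact k-mer seeds between the sequence and itself / its reverse
//      complement (trivial main-diagonal seeds excluded, mirror halves
//      visited once);
//   2. gapped x-drop extension (affine gaps) in both directions to locate
//      alignment endpoints;
//   3. banded affine Needleman-Wunsch over the located segment pair to count
//      matched columns and aligned columns (identity = matches / columns,
//      gap columns included);
//   4. canonical ordering (leftmost arm first), deduplication, containment
//      pruning, and the length/identity filter.
//
// All coordinates are 0-based half-open on the input sequence.

namespace {

const int NBASE = 5; // A,C,G,T,N

inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return 4;
  }
}

std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

std::vector<int> revcomp(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? 3 - b : 4;
  }
  return r;
}

inline int score_pair(int a, int b, int match, int mismatch) {
  if (a >= 4 || b >= 4) return mismatch; // N never matches
  return (a == b) ? match : mismatch;
}

struct Hsp {
  int qb, qe, tb, te;   // half-open, q on query, t on target
  int matches, columns; // alignment column stats
  long score;
};

const long NEG = -1000000000L;

// Gapped x-drop extension from an anchor, in one direction.
// dir=+1 extends to the right starting at (q0, t0); dir=-1 extends left
// ending at (q0-1, t0-1). Returns offsets (dq, dt) of the best endpoint:
// the extension consumes dq query bases and dt target bases.
//
// diag_limit >= 0 restricts the path for same-strand self-alignment: cells
// on or beyond the main diagonal (where a base would be compared against
// itself, a guaranteed match) are forbidden. The constraint is
// consumed_query - consumed_target < diag_limit for dir=+1 and
// consumed_target - consumed_query < diag_limit for dir=-1, with diag_limit
// equal to the seed's diagonal offset.
void xdrop_extend(const std::vector<int>& Q, const std::vector<int>& T,
                  int q0, int t0, int dir,
                  int match, int mismatch, int gap_open, int gap_extend,
                  int xdrop, int diag_limit, int& best_dq, int& best_dt) {
  int qlim = (dir > 0) ? (int)Q.size() - q0 : q0;
  int tlim = (dir > 0) ? (int)T.size() - t0 : t0;
  best_dq = 0; best_dt = 0;
  if (qlim == 0 || tlim == 0) return;

  // DP over rows i = consumed query bases; columns j = consumed target bases.
  // M[j]: best score ending in a match/mismatch; best[j]: max of states.
  // Band tracked as [lo, hi] of live columns per row, pruned by x-drop.
  long best_score = 0;
  int lo = 0, hi = 0;
  std::vector<long> M(tlim + 1, NEG), Ix(tlim + 1, NEG), Iy(tlim + 1, NEG);
  // row 0: gaps in query (consume target only)
  M[0] = 0;
  for (int j = 1; j <= tlim; ++j) {
    Iy[j] = -gap_open - (long)gap_extend * j;
    if (Iy[j] < best_score - xdrop) { break; }
    hi = j;
  }
  std::vector<long> nM(tlim + 1), nIx(tlim + 1), nIy(tlim + 1);

  for (int i = 1; i <= qlim; ++i) {
    int nlo = tlim + 1, nhi = -1;
    // candidate columns for this row: [lo, hi+1]
    int clo = lo, chi = std::min(hi + 1, tlim);
    for (int j = clo; j <= chi; ++j) { nM[j] = nIx[j] = nIy[j] = NEG; }
    for (int j = clo; j <= chi; ++j) {
      long m = NEG, ix = NEG, iy = NEG;
      // Ix: gap in target (consume query base)
      {
        long a = (M[j] != NEG) ? M[j] - gap_open - gap_extend : NEG;
        long b = (Ix[j] != NEG) ? Ix[j] - gap_extend : NEG;
        ix = std::max(a, b);
      }
      // Iy: gap in query (consume target base)
      if (j > 0) {
        long a = (nM[j - 1] != NEG) ? nM[j - 1] - gap_open - gap_extend : NEG;
        long b = (nIy[j - 1] != NEG) ? nIy[j - 1] - gap_extend : NEG;
        iy = std::max(a, b);
      }
      // M: diagonal
      if (j > 0) {
        long d = std::max(M[j - 1], std::max(Ix[j - 1], Iy[j - 1]));
        if (d != NEG) {
          int qi = (dir > 0) ? q0 + i - 1 : q0 - i;
          int tj = (dir > 0) ? t0 + j - 1 : t0 - j;
          m = d + score_pair(Q[qi], T[tj], match, mismatch);
        }
      }
      long cell = std::max(m, std::max(ix, iy));
      bool off_diag_ok = true;
      if (diag_limit >= 0) {
        int shift = (dir > 0) ? (i - j) : (j - i);
        if (shift >= diag_limit) off_diag_ok = false;
      }
      if (!off_diag_ok || cell == NEG || cell < best_score - xdrop) {
        nM[j] = nIx[j] = nIy[j] = NEG;
        continue;
      }
      nM[j] = m; nIx[j] = ix; nIy[j] = iy;
      if (j < nlo) nlo = j;
      if (j > nhi) nhi = j;
      if (m > best_score) { best_score = m; best_dq = i; best_dt = j; }
    }
    if (nhi < 0) break; // row dead
    lo = nlo; hi = nhi;
    std::swap(M, nM); std::swap(Ix, nIx); std::swap(Iy, nIy);
    // cells outside [lo,hi] in the stale buffers must not leak
    if (lo > 0) { M[lo - 1] = Ix[lo - 1] = Iy[lo - 1] = NEG; }
    if (hi + 1 <= tlim) { M[hi + 1] = Ix[hi + 1] = Iy[hi + 1] = NEG; }
  }
}

// Banded global (Needleman-Wunsch) affine alignment of Q[qb,qe) vs T[tb,te),
// counting matched columns and total columns of the optimal alignment.
void banded_nw_stats(const std::vector<int>& Q, const std::vector<int>& T,
                     int qb, int qe, int tb, int te,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int& matches, int& columns, long& score) {
  int n = qe - qb, m = te - tb;
  int band = std::abs(n - m) + 100;
  // state matrices within band: column index j in [max(0,i-band), min(m,i+band)]
  int width = 2 * band + 1;
  const int INEG = -1000000000;
  std::vector<std::vector<int>> Mm(n + 1, std::vector<int>(width, INEG)),
      Ix(n + 1, std::vector<int>(width, INEG)),
      Iy(n + 1, std::vector<int>(width, INEG));
  std::vector<std::vector<uint8_t>> tbM(n + 1, std::vector<uint8_t>(width, 0)),
      tbIx(n + 1, std::vector<uint8_t>(width, 0)),
      tbIy(n + 1, std::vector<uint8_t>(width, 0));
  auto col = [&](int i, int j) { return j - i + band; }; // band offset
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && j - i >= -band && j - i <= band;
  };
  Mm[0][col(0, 0)] = 0;
  for (int j = 1; inband(0, j); ++j) {
    Iy[0][col(0, j)] = -gap_open - gap_extend * j;
    tbIy[0][col(0, j)] = (j == 1) ? 0 : 1; // 0: from M, 1: from Iy
  }
  for (int i = 1; i <= n; ++i) {
    if (inband(i, 0)) {
      Ix[i][col(i, 0)] = -gap_open - gap_extend * i;
      tbIx[i][col(i, 0)] = (i == 1) ? 0 : 1;
    }
    int jlo = std::max(1, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int c = col(i, j);
      // Ix: gap in target (from row i-1, same j)
      if (inband(i - 1, j)) {
        int cu = col(i - 1, j);
        int a = (Mm[i - 1][cu] != INEG) ? Mm[i - 1][cu] - gap_open - gap_extend : INEG;
        int b = (Ix[i - 1][cu] != INEG) ? Ix[i - 1][cu] - gap_extend : INEG;
        if (a >= b) { Ix[i][c] = a; tbIx[i][c] = 0; }
        else { Ix[i][c] = b; tbIx[i][c] = 1; }
      }
      // Iy: gap in query (from same i, j-1)
      if (inband(i, j - 1)) {
        int cl = col(i, j - 1);
        int a = (Mm[i][cl] != INEG) ? Mm[i][cl] - gap_open - gap_extend : INEG;
        int b = (Iy[i][cl] != INEG) ? Iy[i][cl] - gap_extend : INEG;
        if (a >= b) { Iy[i][c] = a; tbIy[i][c] = 0; }
        else { Iy[i][c] = b; tbIy[i][c] = 1; }
      }
      // M: diagonal
      if (inband(i - 1, j - 1)) {
        int cd = col(i - 1, j - 1);
        int d = Mm[i - 1][cd]; uint8_t t = 0;
        if (Ix[i - 1][cd] > d) { d = Ix[i - 1][cd]; t = 1; }
        if (Iy[i - 1][cd] > d) { d = Iy[i - 1][cd]; t = 2; }
        if (d != INEG) {
          Mm[i][c] = d + score_pair(Q[qb + i - 1], T[tb + j - 1], match, mismatch);
          tbM[i][c] = t;
        }
      }
    }
  }
  // endpoint
  int c = col(n, m);
  int sM = Mm[n][c], sIx = Ix[n][c], sIy = Iy[n][c];
  int state = 0; score = sM;
  if (sIx > score) { score = sIx; state = 1; }
  if (sIy > score) { score = sIy; state = 2; }
  // traceback
  matches = 0; columns = 0;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int cc = col(i, j);
    if (state == 0) {
      ++columns;
      if (Q[qb + i - 1] == T[tb + j - 1] && Q[qb + i - 1] < 4) ++matches;
      uint8_t t = tbM[i][cc];
      --i; --j; state = t;
    } else if (state == 1) {
      ++columns;
      uint8_t t = tbIx[i][cc];
      --i; state = (t == 0) ? 0 : 1;
    } else {
      ++columns;
      uint8_t t = tbIy[i][cc];
      --j; state = (t == 0) ? 0 : 2;
    }
  }
}

// seed index: positions of each k-mer in the query
typedef std::unordered_map<uint64_t, std::vector<int>> KmerIndex;

bool kmer_at(const std::vector<int>& v, int pos, int k, uint64_t& key) {
  uint64_t h = 0;
  for (int i = 0; i < k; ++i) {
    int b = v[pos + i];
    if (b >= 4) return false;
    h = h * 4 + b;
  }
  key = h;
  return true;
}

void collect_hsps(const std::vector<int>& Q, const std::vector<int>& T,
                  bool self_same_strand, int k,
                  int match, int mismatch, int gap_open, int gap_extend,
                  int xdrop, std::vector<Hsp>& out) {
  int n = (int)Q.size();
  if (n < k) return;
  KmerIndex idx;
  for (int i = 0; i + k <= n; ++i) {
    uint64_t key;
    if (kmer_at(Q, i, k, key)) idx[key].push_back(i);
  }
  // per-diagonal extent already covered by an accepted extension
  std::unordered_map<long, int> diag_end;
  int tn = (int)T.size();
  for (int j = 0; j + k <= tn; ++j) {
    uint64_t key;
    if (!kmer_at(T, j, k, key)) continue;
    KmerIndex::const_iterator it = idx.find(key);
    if (it == idx.end()) continue;
    for (int i : it->second) {
      if (self_same_strand) {
        if (i >= j) continue; // canonical half, skips trivial diagonal
      }
      long d = (long)j - i;
      std::unordered_map<long, int>::iterator de = diag_end.find(d);
      if (de != diag_end.end() && i < de->second) continue;
      // extend; same-strand self comparison must stay strictly below the
      // main diagonal (a base compared to itself is a guaranteed match)
      int dl = self_same_strand ? (int)d : -1;
      int rdq, rdt, ldq, ldt;
      xdrop_extend(Q, T, i + k, j + k, +1, match, mismatch, gap_open,
                   gap_extend, xdrop, dl, rdq, rdt);
      xdrop_extend(Q, T, i, j, -1, match, mismatch, gap_open, gap_extend,
                   xdrop, dl, ldq, ldt);
      Hsp h;
      h.qb = i - ldq; h.qe = i + k + rdq;
      h.tb = j - ldt; h.te = j + k + rdt;
      banded_nw_stats(Q, T, h.qb, h.qe, h.tb, h.te, match, mismatch, gap_open,
                      gap_extend, h.matches, h.columns, h.score);
      out.push_back(h);
      int cov_end = h.qe;
      std::unordered_map<long, int>::iterator de2 = diag_end.find(d);
      if (de2 == diag_end.end() || cov_end > de2->second) diag_end[d] = cov_end;
    }
  }
}

struct Arm { int q1, q2, s1, s2; bool opposite; };

} // namespace

// [[Rcpp::export(name = ".cpp_self_align")]]
DataFrame cpp_self_align(std::string sequence, int min_len, double min_ident,
                         int seed_len, int match, int mismatch, int gap_open,
                         int gap_extend, int xdrop) {
  std::vector<int> S = encode(sequence);
  int n = (int)S.size();
  std::vector<Hsp> same, opp;
  collect_hsps(S, S, true, seed_len, match, mismatch, gap_open, gap_extend,
               xdrop, same);
  std::vector<int> R = revcomp(S);
  collect_hsps(S, R, false, seed_len, match, mismatch, gap_open, gap_extend,
               xdrop, opp);

  struct Rec { int q1, q2, s1, s2; bool opposite; int matches, columns; long score; };
  std::vector<Rec> recs;
  for (const Hsp& h : same) {
    Rec r; r.opposite = false;
    r.q1 = h.qb; r.q2 = h.qe; r.s1 = h.tb; r.s2 = h.te;
    r.matches = h.matches; r.columns = h.columns; r.score = h.score;
    if (r.q1 > r.s1 || (r.q1 == r.s1 && r.q2 > r.s2)) {
      std::swap(r.q1, r.s1); std::swap(r.q2, r.s2);
    }
    // trivial self-identity
    if (r.q1 == r.s1 && r.q2 == r.s2) continue;
    recs.push_back(r);
  }
  for (const Hsp& h : opp) {
    // target was revcomp(S): T interval [tb,te) maps to S interval [n-te, n-tb)
    Rec r; r.opposite = true;
    r.q1 = h.qb; r.q2 = h.qe;
    r.s1 = n - h.te; r.s2 = n - h.tb;
    r.matches = h.matches; r.columns = h.columns; r.score = h.score;
    if (r.q1 > r.s1 || (r.q1 == r.s1 && r.q2 > r.s2)) {
      std::swap(r.q1, r.s1); std::swap(r.q2, r.s2);
    }
    recs.push_back(r);
  }

  // filter: strict > on both thresholds
  std::vector<Rec> keep;
  for (const Rec& r : recs) {
    if (r.columns <= min_len) continue;
    double ident = 100.0 * r.matches / r.columns;
    if (!(ident > min_ident)) continue;
    keep.push_back(r);
  }
  // dedupe exact, then drop hits contained in a better-or-equal hit
  std::sort(keep.begin(), keep.end(), [](const Rec& a, const Rec& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.q1 != b.q1) return a.q1 < b.q1;
    if (a.s1 != b.s1) return a.s1 < b.s1;
    return (a.q2 - a.q1) < (b.q2 - b.q1);
  });
  std::vector<Rec> final_;
  for (const Rec& r : keep) {
    bool redundant = false;
    for (const Rec& f : final_) {
      if (f.opposite != r.opposite) continue;
      if (f.q1 == r.q1 && f.q2 == r.q2 && f.s1 == r.s1 && f.s2 == r.s2) {
        redundant = true; break;
      }
      if (f.q1 <= r.q1 && f.q2 >= r.q2 && f.s1 <= r.s1 && f.s2 >= r.s2 &&
          f.score >= r.score) {
        redundant = true; break;
      }
    }
    if (!redundant) final_.push_back(r);
  }

  int m = (int)final_.size();
  IntegerVector q_start(m), q_end(m), s_start(m), s_end(m), aln_length(m),
      matches(m);
  CharacterVector strand(m);
  NumericVector identity(m), score(m);
  for (int i = 0; i < m; ++i) {
    const Rec& r = final_[i];
    q_start[i] = r.q1; q_end[i] = r.q2;
    s_start[i] = r.s1; s_end[i] = r.s2;
    strand[i] = r.opposite ? "opposite" : "same";
    aln_length[i] = r.columns;
    matches[i] = r.matches;
    identity[i] = 100.0 * r.matches / r.columns;
    score[i] = (double)r.score;
  }
  return DataFrame::create(
      _["q_start"] = q_start, _["q_end"] = q_end, _["s_start"] = s_start,
      _["s_end"] = s_end, _["strand"] = strand, _["identity_pct"] = identity,
      _["aln_length"] = aln_length, _["matches"] = matches,
      _["score"] = score, _["stringsAsFactors"] = false);
}
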