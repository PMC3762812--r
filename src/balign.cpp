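#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Banded affine-gap pairwise alignment (Gotoh) with traceback, used where
// a seeding stage has already constrained the alignment diagonal: exact
// within the band, linear-ish memory via band storage. Sequences are
// integer-coded (0..3; negative codes are unalignable and score -1000 so
// alignments never pass through N/masked bases).
//
// mode 0 = global (end gaps penalized), mode 1 = local (Smith-Waterman;
// best path may start/end anywhere).
// The band restricts j - i (position in b minus position in a) to
// [lo, hi]. For global mode the caller must ensure lo <= 0, hi >= m - n.
//
// Returns 1-based inclusive aligned spans on both sequences, exact match
// and gap statistics, and the traceback as a move vector (0 = M,
// 1 = gap in b [consumes a], 2 = gap in a [consumes b]).

static const int NEG = -100000000;

// [[Rcpp::export(name = ".band_align")]]
List band_align(IntegerVector a, IntegerVector b, int mode, int lo, int hi,
                int match, int mismatch, int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  if (lo > hi) stop("empty band");
  const int W = hi - lo + 1;
  const int open_ext = gap_open + gap_extend;

  std::vector<int> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<int> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  // direction bits: M: 0 from M, 1 from X, 2 from Y, 3 fresh start
  std::vector<uint8_t> dM((size_t)(n + 1) * W, 0), dX((size_t)(n + 1) * W, 0),
      dY((size_t)(n + 1) * W, 0);

  auto col_of = [&](int i, int j) { return j - (i + lo); };

  // row 0
  for (int j = std::max(0, lo); j <= std::min(m, hi); ++j) {
    int c = col_of(0, j);
    if (j == 0) {
      Mp[c] = 0;
    } else if (mode == 0) {
      Yp[c] = -(gap_open + gap_extend * j);
      dY[c] = (j == 1) ? 0 : 2;
    }
    if (mode == 1) Mp[c] = NEG; // local: fresh starts handled per cell
  }

  int best = (mode == 0) ? NEG : 0;
  int best_i = 0, best_j = 0, best_state = 0;

  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(0, i + lo), jhi = std::min(m, i + hi);
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    const size_t off = (size_t)i * W;
    const size_t offp = (size_t)(i - 1) * W;
    // j == 0 boundary (global left edge)
    if (jlo == 0) {
      int c0 = col_of(i, 0);
      if (mode == 0) {
        Xc[c0] = -(gap_open + gap_extend * i);
        dX[off + c0] = (i == 1) ? 0 : 1;
      }
    }
    for (int j = std::max(1, jlo); j <= jhi; ++j) {
      const int c = col_of(i, j);
      // X: gap in b, from (i-1, j) -> same j, col c + 1 in previous row
      if (c + 1 < W) {
        const int fromM = (Mp[c + 1] <= NEG / 2) ? NEG : Mp[c + 1] - open_ext;
        const int fromX = (Xp[c + 1] <= NEG / 2) ? NEG : Xp[c + 1] - gap_extend;
        if (fromM >= fromX) {
          Xc[c] = fromM;
          dX[off + c] = 0;
        } else {
          Xc[c] = fromX;
          dX[off + c] = 1;
        }
      }
      // Y: gap in a, from (i, j-1) -> col c - 1 in current row
      if (c - 1 >= 0) {
        const int fromM = (Mc[c - 1] <= NEG / 2) ? NEG : Mc[c - 1] - open_ext;
        const int fromY = (Yc[c - 1] <= NEG / 2) ? NEG : Yc[c - 1] - gap_extend;
        if (fromM >= fromY) {
          Yc[c] = fromM;
          dY[off + c] = 0;
        } else {
          Yc[c] = fromY;
          dY[off + c] = 2;
        }
      }
      // M: diagonal from (i-1, j-1) -> same col c in previous row
      const int ai = a[i - 1], bj = b[j - 1];
      const int sub = (ai < 0 || bj < 0) ? -1000
                      : (ai == bj ? match : mismatch);
      int bestprev = Mp[c];
      uint8_t dir = 0;
      if (Xp[c] > bestprev) { bestprev = Xp[c]; dir = 1; }
      if (Yp[c] > bestprev) { bestprev = Yp[c]; dir = 2; }
      if (mode == 1 && 0 > bestprev) { bestprev = 0; dir = 3; }
      Mc[c] = (bestprev <= NEG / 2) ? NEG : bestprev + sub;
      dM[off + c] = dir;
      if (mode == 1 && Mc[c] > best) {
        best = Mc[c];
        best_i = i;
        best_j = j;
        best_state = 0;
      }
    }
    std::swap(Mp, Mc);
    std::swap(Xp, Xc);
    std::swap(Yp, Yc);
  }

  if (mode == 0) {
    const int c = col_of(n, m);
    if (c < 0 || c >= W) stop("band does not cover the global end cell");
    best = Mp[c];
    best_state = 0;
    if (Xp[c] > best) { best = Xp[c]; best_state = 1; }
    if (Yp[c] > best) { best = Yp[c]; best_state = 2; }
    best_i = n;
    best_j = m;
  }

  // traceback
  std::vector<int> ops;
  int i = best_i, j = best_j, state = best_state;
  int matches = 0, qgap = 0, sgap = 0, gap_count = 0;
  bool done = false;
  while (!done) {
    if (mode == 0 && i == 0 && j == 0) break;
    const int c = col_of(i, j);
    const size_t off = (size_t)i * W;
    if (state == 0) { // M
      if (mode == 1 && i == 0) break;
      uint8_t d = dM[off + c];
      ops.push_back(0);
      if (i >= 1 && j >= 1 && a[i - 1] >= 0 && a[i - 1] == b[j - 1]) {
        ++matches;
      }
      --i;
      --j;
      if (d == 3) {
        done = true; // local fresh start
      } else {
        state = d;
      }
      if (mode == 0 && i == 0 && j == 0) done = true;
    } else if (state == 1) { // X: consumes a, gap in b
      uint8_t d = dX[off + c];
      ops.push_back(1);
      ++sgap;
      --i;
      if (d == 0) {
        ++gap_count;
        state = 0;
      }
      if (mode == 0 && i == 0 && j == 0) done = true;
    } else { // Y: consumes b, gap in a
      uint8_t d = dY[off + c];
      ops.push_back(2);
      ++qgap;
      --j;
      if (d == 0) {
        ++gap_count;
        state = 0;
      }
      if (mode == 0 && i == 0 && j == 0) done = true;
    }
    if (i < 0 || j < 0) stop("traceback escaped the matrix");
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(
    _["score"] = best,
    _["q1"] = i + 1, _["q2"] = best_i,
    _["s1"] = j + 1, _["s2"] = best_j,
    _["matches"] = matches,
    _["aln_len"] = (int)ops.size(),
    _["qgap"] = qgap, _["sgap"] = sgap,
    _["gap_count"] = gap_count,
    _["ops"] = IntegerVector(ops.begin(), ops.end())
  );
}
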