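#include <Rcpp.h>
using namespace Rcpp;

// Local wraparound dynamic programming of a sequence window against a
// cyclic consensus of period p (tandem-repeat verification, TRF-style
// scoring with linear gap costs). The consensus is treated as circular:
// column j-1 wraps from column 0 to column p-1, which lets the alignment
// pass through an arbitrary number of consensus copies. Within-row
// (horizontal) wraparound is resolved by two relaxation sweeps per row.
//
// seq:  integer codes 0..3 (-1 for N, always a mismatch)
// cons: integer codes 0..3, length = period
// Returns the best local path: score, 0-based half-open window span
// [qstart, qend), the first consensus column consumed (0-based), match
// count, consensus columns consumed, and total alignment columns.
// [[Rcpp::export(name = ".wrap_align")]]
List wrap_align(IntegerVector seq, IntegerVector cons,
                int match, int mismatch, int indel) {
  const int n = seq.size();
  const int p = cons.size();
  std::vector<int> S_prev(p, 0), S_cur(p, 0);
  std::vector<int> SR_prev(p, 0), SR_cur(p, 0);   // start row of local path
  std::vector<int> SC_prev(p, 0), SC_cur(p, 0);   // col *before* path start
  std::vector<int> M_prev(p, 0), M_cur(p, 0);     // matches
  std::vector<int> C_prev(p, 0), C_cur(p, 0);     // consensus cols consumed
  std::vector<int> A_prev(p, 0), A_cur(p, 0);     // alignment columns

  for (int j = 0; j < p; ++j) { SC_prev[j] = j; }

  int best = 0, best_i = 0, best_j = 0;
  int bSR = 0, bSC = 0, bM = 0, bC = 0, bA = 0;

  for (int i = 1; i <= n; ++i) {
    const int x = seq[i - 1];
    for (int j = 0; j < p; ++j) {
      const int jm = (j == 0) ? p - 1 : j - 1;
      const bool eq = (x >= 0 && x == cons[j]);
      // diagonal from previous row
      int s = S_prev[jm] + (eq ? match : mismatch);
      int sr = SR_prev[jm], sc = SC_prev[jm];
      int m = M_prev[jm] + (eq ? 1 : 0), c = C_prev[jm] + 1,
          a = A_prev[jm] + 1;
      // vertical: gap in consensus (sequence char unmatched)
      const int sv = S_prev[j] + indel;
      if (sv > s) {
        s = sv; sr = SR_prev[j]; sc = SC_prev[j];
        m = M_prev[j]; c = C_prev[j]; a = A_prev[j] + 1;
      }
      if (s <= 0) { // restart: path begins after row i-1 at column j
        s = 0; sr = i; sc = j; m = 0; c = 0; a = 0;
      }
      S_cur[j] = s; SR_cur[j] = sr; SC_cur[j] = sc;
      M_cur[j] = m; C_cur[j] = c; A_cur[j] = a;
    }
    // horizontal moves (gap in sequence, consensus col consumed) with
    // wraparound: two sweeps suffice
    for (int sweep = 0; sweep < 2; ++sweep) {
      for (int j = 0; j < p; ++j) {
        const int jm = (j == 0) ? p - 1 : j - 1;
        const int sh = S_cur[jm] + indel;
        if (sh > S_cur[j]) {
          S_cur[j] = sh; SR_cur[j] = SR_cur[jm]; SC_cur[j] = SC_cur[jm];
          M_cur[j] = M_cur[jm]; C_cur[j] = C_cur[jm] + 1;
          A_cur[j] = A_cur[jm] + 1;
        }
      }
    }
    for (int j = 0; j < p; ++j) {
      if (S_cur[j] > best) {
        best = S_cur[j]; best_i = i; best_j = j;
        bSR = SR_cur[j]; bSC = SC_cur[j];
        bM = M_cur[j]; bC = C_cur[j]; bA = A_cur[j];
      }
    }
    std::swap(S_prev, S_cur); std::swap(SR_prev, SR_cur);
    std::swap(SC_prev, SC_cur); std::swap(M_prev, M_cur);
    std::swap(C_prev, C_cur); std::swap(A_prev, A_cur);
  }

  return List::create(
    _["score"] = best,
    _["qstart"] = bSR,          // 0-based: first sequence row consumed
    _["qend"] = best_i,         // 0-based half-open
    _["cstart"] = (bSC + 1) % p, // first consensus column consumed
    _["matches"] = bM,
    _["cons_cols"] = bC,
    _["aln_cols"] = bA,
    _["end_col"] = best_j
  );
}
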