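#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Semi-global alignment of a query (fully aligned) against a reference with
// free reference ends, restricted to diagonals j - i in [diag_lo, diag_hi].
// Unit scores: match +1, mismatch -1, gap -1 (linear).
//
// The DP maximizes (score, matches) lexicographically. For a fixed optimal
// score S the alignment-column count equals 2*M - S, so identity M/(2M - S)
// is strictly increasing in M: lexicographic maximization realizes the
// "highest identity among optimal-score alignments" tie-break
// deterministically. The pair is packed into one int64 (score in the high
// bits, matches in the low 32) so each DP cell is a plain max of three
// integers.
//
// Sequences are integer-coded (A=0, C=1, G=2, T=3). Passing diag_lo = -n and
// diag_hi = m makes the band cover the full matrix (exhaustive DP).

static const int64_t NEG = INT64_MIN / 4;
static const int64_t ONE_SCORE = int64_t(1) << 32;

// [[Rcpp::export]]
List semiglobal_align_cpp(IntegerVector q, IntegerVector r,
                          int diag_lo, int diag_hi) {
  const int n = q.size(), m = r.size();
  if (n == 0) stop("empty query");
  if (m == 0) stop("empty reference");

  // Clamp the diagonal window so both the first and last DP rows contain at
  // least one in-matrix cell (a complete query path exists inside the band).
  if (diag_lo < -n) diag_lo = -n;
  if (diag_hi > m) diag_hi = m;
  if (diag_lo > m - n) diag_lo = m - n;
  if (diag_lo < -n) diag_lo = -n;
  if (diag_hi < 0) diag_hi = 0;
  if (diag_hi < diag_lo) diag_hi = diag_lo;

  const int W = diag_hi - diag_lo + 1;
  const double cells = (double)(n + 1) * (double)W;
  if (cells > 1.5e9) stop("alignment matrix too large (query %d, band width %d)", n, W);

  const int *qp = INTEGER(q), *rp = INTEGER(r);
  std::vector<int64_t> Vprev(W + 1), Vcur(W + 1);  // +1: sentinel for w+1 access
  std::vector<uint8_t> tb((size_t)(n + 1) * W);    // 0 stop, 1 diag, 2 up, 3 left

  for (int w = 0; w < W; ++w) {
    const int j = diag_lo + w;                     // row 0: i == 0 so j == d
    Vprev[w] = (j >= 0 && j <= m) ? 0 : NEG;
    tb[w] = 0;
  }
  Vprev[W] = NEG;

  for (int i = 1; i <= n; ++i) {
    const int qi = qp[i - 1];
    const int off = i + diag_lo;                   // j = off + w
    int wlo = 0 > -off ? 0 : -off;                 // j >= 0
    int whi = (W - 1) < (m - off) ? (W - 1) : (m - off);  // j <= m
    uint8_t *tbrow = &tb[(size_t)i * W];
    for (int w = 0; w < wlo; ++w) { Vcur[w] = NEG; tbrow[w] = 0; }
    for (int w = whi + 1; w < W; ++w) { Vcur[w] = NEG; tbrow[w] = 0; }
    Vcur[W] = NEG;
    for (int w = wlo; w <= whi; ++w) {
      const int j = off + w;
      int64_t best = NEG;
      uint8_t mv = 0;
      if (j >= 1) {                                // diagonal
        const int64_t add = (qi == rp[j - 1]) ? (ONE_SCORE + 1) : -ONE_SCORE;
        best = Vprev[w] + add;
        mv = 1;
      }
      const int64_t up = Vprev[w + 1] - ONE_SCORE; // query base vs gap
      if (up > best) { best = up; mv = 2; }
      if (w > wlo) {                               // gap vs reference base
        const int64_t left = Vcur[w - 1] - ONE_SCORE;
        if (left > best) { best = left; mv = 3; }
      }
      Vcur[w] = best;
      tbrow[w] = mv;
    }
    std::swap(Vprev, Vcur);
  }

  // Best end cell in the last row: packed (score, matches), ties to the
  // smallest reference end coordinate.
  int bw = -1;
  int64_t bv = NEG;
  for (int w = 0; w < W; ++w) {
    const int j = n + diag_lo + w;
    if (j < 0 || j > m || Vprev[w] <= NEG / 2) continue;
    if (Vprev[w] > bv) { bv = Vprev[w]; bw = w; }
  }
  if (bw < 0) stop("no feasible alignment inside the band");

  int matches = 0, mismatches = 0, insertions = 0, deletions = 0;
  int i = n, w = bw;
  const int ref_end = n + diag_lo + bw;
  while (i > 0) {
    const uint8_t mv = tb[(size_t)i * W + w];
    if (mv == 1) {
      const int j = i + diag_lo + w;
      if (qp[i - 1] == rp[j - 1]) ++matches; else ++mismatches;
      --i;                        // diagonal keeps w
    } else if (mv == 2) {
      ++insertions; --i; ++w;
    } else if (mv == 3) {
      ++deletions; --w;
    } else {
      stop("corrupt traceback");  // unreachable for feasible end cells
    }
  }
  const int ref_start = i + diag_lo + w;  // i == 0

  const int score = (int)(bv >> 32);  // arithmetic shift == floor: exact for M in [0, 2^32)
  return List::create(
    _["score"] = score, _["matches"] = matches, _["mismatches"] = mismatches,
    _["insertions"] = insertions, _["deletions"] = deletions,
    _["ref_start"] = ref_start, _["ref_end"] = ref_end);
}

// Minimum edit distance of `pattern` against any substring of `text`
// (free text ends, pattern fully consumed). Used for barcode matching.

// [[Rcpp::export]]
int edit_infix_cpp(IntegerVector pattern, IntegerVector text) {
  const int n = pattern.size(), m = text.size();
  if (n == 0) return 0;
  if (m == 0) return n;
  std::vector<int> prev(m + 1, 0), cur(m + 1);
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const int pi = pattern[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int sub = prev[j - 1] + (pi == text[j - 1] ? 0 : 1);
      const int del = prev[j] + 1;   // pattern base unmatched
      const int ins = cur[j - 1] + 1;
      int v = sub;
      if (del < v) v = del;
      if (ins < v) v = ins;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  int best = prev[0];
  for (int j = 1; j <= m; ++j) if (prev[j] < best) best = prev[j];
  return best;
}
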