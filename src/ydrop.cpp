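// y-drop banded affine-gap extension.
//
// One-directional extension over t[0..n) x q[0..m) starting from the
// implicit origin cell (0,0) with score 0 (the anchor pair itself is scored
// by the caller). Three affine states per cell:
//   M  - last column aligned a target char to a query char,
//   Ix - last column consumed a query char only (gap in target),
//   Iy - last column consumed a target char only (gap in query).
// A gap of length L costs gap_open + L * gap_extend. Per target row only an
// active window of query columns is kept: columns whose best state falls
// more than y_drop below the running maximum are pruned, and the extension
// terminates when a row's window empties. Tie-breaking is fixed — prefer
// the diagonal move, then the horizontal (query-consuming) move, then the
// vertical — identically in every call, so forward and backward passes
// cannot disagree on equally scoring paths.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

struct Row {
  int lo, hi;           // inclusive window of j
  size_t off;           // offset into traceback store
};

// packed traceback: 2 bits per state source (0=M, 1=Ix, 2=Iy, 3=origin/none)
static inline uint8_t pack(int msrc, int xsrc, int ysrc) {
  return (uint8_t)(msrc | (xsrc << 2) | (ysrc << 4));
}

// [[Rcpp::export(name = ".ydrop_extend_dir")]]
List ydrop_extend_dir(IntegerVector t, IntegerVector q, IntegerMatrix sub,
                      int gap_open, int gap_extend, double y_drop,
                      double max_cells = 5e7) {
  const int n = t.size(), m = q.size();
  const int open_cost = gap_open + gap_extend;
  const bool finite_drop = R_finite(y_drop);
  const long long ydrop_ll = finite_drop ? (long long)y_drop : 0;

  std::vector<int> Mrow(m + 1), Xrow(m + 1), Yrow(m + 1);
  std::vector<int> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<Row> rows;
  std::vector<uint8_t> tb;
  rows.reserve(256);
  tb.reserve(4096);

  int best = 0, best_i = 0, best_j = 0, best_state = 0;
  int lo = 0, hi = 0;

  // row 0: gaps in target along the query axis
  Mprev[0] = 0; Xprev[0] = NEG; Yprev[0] = NEG;
  {
    rows.push_back({0, 0, 0});
    tb.push_back(pack(3, 3, 3));
    int j = 1;
    while (j <= m) {
      int x = (j == 1) ? -open_cost : Xprev[j - 1] - gap_extend;
      if (finite_drop && best - x > ydrop_ll) break;
      Mprev[j] = NEG; Yprev[j] = NEG; Xprev[j] = x;
      tb.push_back(pack(3, j == 1 ? 0 : 1, 3));
      ++j;
    }
    hi = j - 1;
    rows[0].hi = hi;
  }

  double cells = hi + 1;
  for (int i = 1; i <= n; ++i) {
    int new_lo = -1, new_hi = -1;
    size_t off = tb.size();
    // window may extend one column left of nothing (lo stays), and right by
    // arbitrary Ix chains; iterate j from lo to m, stopping once past the
    // previous window with the score dead.
    int jstart = lo;  // cell (i, lo) can be reached from (i-1, lo) by Iy
    int prev_hi = hi;
    int row_best = NEG;
    for (int j = jstart; j <= m; ++j) {
      int mm = NEG, xx = NEG, yy = NEG;
      int msrc = 3, xsrc = 3, ysrc = 3;
      if (j > jstart) {
        // horizontal from current row j-1
        int fromM = Mrow[j - 1] - open_cost;
        int fromX = Xrow[j - 1] - gap_extend;
        int fromY = Yrow[j - 1] - open_cost;
        xx = fromM; xsrc = 0;
        if (fromX > xx) { xx = fromX; xsrc = 1; }
        if (fromY > xx) { xx = fromY; xsrc = 2; }
      }
      if (j >= lo && j <= prev_hi) {
        // vertical from previous row j
        int fromM = Mprev[j] - open_cost;
        int fromX = Xprev[j] - open_cost;
        int fromY = Yprev[j] - gap_extend;
        yy = fromM; ysrc = 0;
        if (fromX > yy) { yy = fromX; ysrc = 1; }
        if (fromY > yy) { yy = fromY; ysrc = 2; }
      }
      if (j >= 1 && j - 1 >= lo && j - 1 <= prev_hi) {
        // diagonal from previous row j-1
        int v = Mprev[j - 1]; msrc = 0;
        if (Xprev[j - 1] > v) { v = Xprev[j - 1]; msrc = 1; }
        if (Yprev[j - 1] > v) { v = Yprev[j - 1]; msrc = 2; }
        if (v > NEG / 2) mm = v + sub(t[i - 1], q[j - 1]);
      }
      int cell = mm, cs = 0;  // tie-break: M first, then Ix, then Iy
      if (xx > cell) { cell = xx; cs = 1; }
      if (yy > cell) { cell = yy; cs = 2; }
      bool alive = cell > NEG / 2 &&
                   (!finite_drop || (long long)best - cell <= ydrop_ll);
      if (!alive && j > prev_hi) {
        // beyond the previous window only Ix chains continue; once dead
        // they only decay, so stop the row here.
        break;
      }
      if (alive) {
        if (new_lo < 0) new_lo = j;
        new_hi = j;
        if (cell > row_best) row_best = cell;
        if (cell > best) {
          best = cell; best_i = i; best_j = j; best_state = cs;
        }
      } else {
        mm = xx = yy = NEG;
      }
      Mrow[j] = mm; Xrow[j] = xx; Yrow[j] = yy;
      tb.push_back(pack(msrc, xsrc, ysrc));
    }
    if (new_lo < 0) break;  // window empty: extension terminated
    rows.push_back({jstart, (int)(jstart + (tb.size() - off) - 1), off});
    // clamp stored window to what was actually written
    lo = new_lo; hi = new_hi;
    // mark pruned leading cells as dead for the next row's reads
    for (int j = jstart; j < new_lo; ++j) { Mrow[j] = Xrow[j] = Yrow[j] = NEG; }
    std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev);
    cells += (double)(hi - jstart + 1);
    if (cells > max_cells)
      stop("y-drop extension exceeded max_cells (%.0f); raise max_cells or use a finite y_drop", max_cells);
  }

  // traceback from (best_i, best_j), choosing the best state there
  std::string ops;
  int i = best_i, j = best_j;
  int state = best_state;
  while (!(i == 0 && j == 0)) {
    uint8_t b = tb[rows[i].off + (j - rows[i].lo)];
    int src;
    if (state == 0) { ops.push_back('M'); src = b & 3; --i; --j; }
    else if (state == 1) { ops.push_back('I'); src = (b >> 2) & 3; --j; }
    else { ops.push_back('D'); src = (b >> 4) & 3; --i; }
    if (src == 3) break;  // reached an origin edge
    state = src;
  }
  std::reverse(ops.begin(), ops.end());

  return List::create(_["score"] = best, _["tlen"] = best_i,
                      _["qlen"] = best_j, _["ops"] = ops);
}
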