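#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a logical matrix.
// Labels are assigned in raster-scan (row-major) discovery order, 1..K.
// connectivity: 8 for foreground regions, 4 for background/hole regions.
// [[Rcpp::export]]
List cc_label_cpp(const LogicalMatrix& m, int connectivity) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> start_row, start_col, size, touches_border;
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx4[4] = {0, -1, 1, 0};
  const int dy4[4] = {-1, 0, 0, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  const int* dx = (connectivity == 8) ? dx8 : dx4;
  const int* dy = (connectivity == 8) ? dy8 : dy4;
  std::vector<int> stack;
  int next = 0;
  for (int r = 0; r < nr; ++r) {      // row-major scan: raster order
    for (int c = 0; c < nc; ++c) {
      if (!m(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      start_row.push_back(r + 1);
      start_col.push_back(c + 1);
      int sz = 0, border = 0;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc2 = idx / nr;
        ++sz;
        if (cr == 0 || cr == nr - 1 || cc2 == 0 || cc2 == nc - 1) border = 1;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + dy[k], c2 = cc2 + dx[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (m(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
      size.push_back(sz);
      touches_border.push_back(border);
    }
  }
  return List::create(_["labels"] = lab, _["n"] = next,
                      _["start_row"] = wrap(start_row),
                      _["start_col"] = wrap(start_col),
                      _["size"] = wrap(size),
                      _["touches_border"] = wrap(touches_border));
}

// Moore-neighbour (radial sweep) boundary tracing of the region
// {lab == id}, starting at its first raster-order pixel.  The 8
// neighbours are scanned clockwise on screen (y down) starting just after
// the backtrack cell; termination by Jacob's criterion (the trace leaves
// the start pixel a second time in the same direction as the first
// departure).  Returns the traced closed polygon as an n x 2 matrix of
// 0-based (x, y) pixel coordinates (x = column rightward, y = row down).
// [[Rcpp::export]]
IntegerMatrix trace_region_cpp(const IntegerMatrix& lab, int id,
                               int start_row, int start_col) {
  const int nr = lab.nrow(), nc = lab.ncol();
  // clockwise neighbour ring starting East: E SE S SW W NW N NE
  const int dx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const int dy[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int sr = start_row - 1, sc = start_col - 1;
  std::vector<int> xs, ys;
  xs.push_back(sc);
  ys.push_back(sr);
  bool isolated = true;
  for (int k = 0; k < 8; ++k) {
    int r2 = sr + dy[k], c2 = sc + dx[k];
    if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && lab(r2, c2) == id)
      isolated = false;
  }
  if (!isolated) {
    int cr = sr, cc2 = sc;
    // backtrack cell: West of the start pixel, which is outside the
    // region because the start pixel is first in raster order.
    int br = sr, bc = sc - 1;
    int first_dir = -1;
    long guard = 8L * nr * nc + 64;
    while (guard-- > 0) {
      // direction index from current pixel to backtrack cell
      int k0 = -1;
      for (int k = 0; k < 8; ++k)
        if (cr + dy[k] == br && cc2 + dx[k] == bc) { k0 = k; break; }
      int found = -1;
      for (int s = 1; s <= 8; ++s) {
        int k = (k0 + s) % 8;
        int r2 = cr + dy[k], c2 = cc2 + dx[k];
        if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && lab(r2, c2) == id) {
          found = k;
          break;
        }
        br = r2;  // last examined non-region cell
        bc = c2;
      }
      if (found < 0) break;  // cannot happen: region is not isolated
      if (cr == sr && cc2 == sc) {
        if (first_dir < 0) first_dir = found;
        else if (found == first_dir) break;  // Jacob's stopping criterion
      }
      cr += dy[found];
      cc2 += dx[found];
      xs.push_back(cc2);
      ys.push_back(cr);
    }
  }
  IntegerMatrix out((int)xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) {
    out((int)i, 0) = xs[i];
    out((int)i, 1) = ys[i];
  }
  return out;
}
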