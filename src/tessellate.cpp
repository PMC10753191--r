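#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nearest-seed tessellation with an inter-cell boundary band and a trim
// radius. For every pixel the two nearest seeds are found; the pixel becomes
// boundary (-1) when it lies within `bw` of the bisector between its two
// nearest seeds or within bw/2 of the trim radius `r_cut`, background (0)
// when farther than r_cut + bw/2 from every seed, and otherwise takes the
// 1-based label of its nearest seed. Coordinates are 1-based (row, col).
// [[Rcpp::export]]
IntegerMatrix tessellate_labels(NumericVector seed_row, NumericVector seed_col,
                                int nrow, int ncol, double bw, double r_cut) {
  const int n = seed_row.size();
  IntegerMatrix out(nrow, ncol);
  const double r_bg = r_cut + bw / 2.0;
  const double r_bnd = r_cut - bw / 2.0;
  for (int j = 0; j < ncol; ++j) {
    const double x = j + 1.0;
    for (int i = 0; i < nrow; ++i) {
      const double y = i + 1.0;
      double best1 = R_PosInf, best2 = R_PosInf;
      int lab1 = 0;
      for (int s = 0; s < n; ++s) {
        const double dy = y - seed_row[s];
        const double dx = x - seed_col[s];
        const double d2 = dy * dy + dx * dx;
        if (d2 < best1) {
          best2 = best1;
          best1 = d2;
          lab1 = s + 1;
        } else if (d2 < best2) {
          best2 = d2;
        }
      }
      const double d1 = std::sqrt(best1);
      const double d2n = std::sqrt(best2);
      int v;
      if (d1 > r_bg) {
        v = 0;
      } else if (d1 > r_bnd) {
        v = -1;
      } else if (d2n - d1 < bw) {
        v = -1;
      } else {
        v = lab1;
      }
      out(i, j) = v;
    }
  }
  return out;
}
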