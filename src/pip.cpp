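#include <Rcpp.h>
using namespace Rcpp;

// Even-odd rule point-in-polygon test for many query points against one
// closed polygon. Points falling exactly on a horizontal-crossing edge are
// counted as inside (the boundary belongs to the gate). The polygon need
// not repeat its first vertex.
// [[Rcpp::export(name = ".pipCpp")]]
LogicalVector pipCpp(NumericVector px, NumericVector py,
                     NumericVector vx, NumericVector vy) {
  const R_xlen_t n = px.size();
  R_xlen_t m = vx.size();
  if (m > 1 && vx[0] == vx[m - 1] && vy[0] == vy[m - 1]) m--;
  LogicalVector inside(n, false);
  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = px[p], y = py[p];
    bool in = false;
    bool onEdge = false;
    for (R_xlen_t i = 0, j = m - 1; i < m; j = i++) {
      const double xi = vx[i], yi = vy[i], xj = vx[j], yj = vy[j];
      if ((yi > y) != (yj > y)) {
        const double xcross = (xj - xi) * (y - yi) / (yj - yi) + xi;
        if (x == xcross) onEdge = true;
        else if (x < xcross) in = !in;
      } else if (yi == y && yj == y) {
        // horizontal edge: point on the segment counts as inside
        if (x >= std::min(xi, xj) && x <= std::max(xi, xj)) onEdge = true;
      }
    }
    inside[p] = in || onEdge;
  }
  return inside;
}
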