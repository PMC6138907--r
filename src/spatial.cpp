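#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sum of edge-correction weights over ordered pairs (i != j) with d_ij <= r_k,
// returned cumulatively over the (strictly increasing) radius grid.
// correction: 0 = none (weight 1), 1 = translation (exact for rectangles):
//   w_ij = (ax * ay) / ((ax - |dx|) * (ay - |dy|))
// Pairs further apart than max(r) are skipped before the sqrt.
// [[Rcpp::export]]
NumericVector kfun_pair_weights(NumericVector x, NumericVector y,
                                NumericVector r, double ax, double ay,
                                int correction) {
  const int n = x.size();
  const int nr = r.size();
  NumericVector acc(nr);
  if (n < 2 || nr == 0) return acc;
  const double rmax = r[nr - 1];
  const double rmax2 = rmax * rmax;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j];
      const double dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 > rmax2) continue;
      const double d = std::sqrt(d2);
      double w = 1.0;
      if (correction == 1)
        w = (ax * ay) / ((ax - std::fabs(dx)) * (ay - std::fabs(dy)));
      // first radius with r >= d receives the (unordered) pair twice
      const int k = std::lower_bound(r.begin(), r.end(), d) - r.begin();
      if (k < nr) acc[k] += 2.0 * w;
    }
  }
  for (int k = 1; k < nr; ++k) acc[k] += acc[k - 1];
  return acc;
}

// Exact nearest-neighbour distance from each query point to the target set,
// via a plane sweep over targets pre-sorted by x (sorting done by the caller).
// Returns one distance per query, in query order.
// [[Rcpp::export]]
NumericVector cross_nn_sweep(NumericVector qx, NumericVector qy,
                             NumericVector tx, NumericVector ty) {
  const int n = qx.size();
  const int m = tx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best2 = R_PosInf;
    const double px = qx[i], py = qy[i];
    int right = std::lower_bound(tx.begin(), tx.end(), px) - tx.begin();
    int left = right - 1;
    while (left >= 0 || right < m) {
      bool advanced = false;
      if (right < m) {
        const double dx = tx[right] - px;
        if (dx * dx <= best2) {
          const double dy = ty[right] - py;
          const double d2 = dx * dx + dy * dy;
          if (d2 < best2) best2 = d2;
          ++right;
          advanced = true;
        } else {
          right = m;
        }
      }
      if (left >= 0) {
        const double dx = px - tx[left];
        if (dx * dx <= best2) {
          const double dy = ty[left] - py;
          const double d2 = dx * dx + dy * dy;
          if (d2 < best2) best2 = d2;
          --left;
          advanced = true;
        } else {
          left = -1;
        }
      }
      if (!advanced) break;
    }
    out[i] = std::sqrt(best2);
  }
  return out;
}
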