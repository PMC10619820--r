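#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Hartigan & Hartigan's dip statistic:
//   dip(F_n) = min over unimodal CDFs G of sup_x |F_n(x) - G(x)|.
//
// Band formulation. For sorted data with distinct values x_1 < ... < x_k,
// cumulative ECDF mass lo_j (at x_j) and pre-jump mass up_j (just left of
// x_j), a unimodal G within distance d of F_n with mode at x_m exists iff
//   (left)  the greatest convex minorant of {(x_j, up_j)}_{j<=m}
//           is >= lo_j - 2d at every j < m, and
//   (right) the least concave majorant of {(x_j, lo_j)}_{j>=m}
//           is <= up_j + 2d at every j > m.
// (G may jump at the mode, so the mode point itself is unconstrained beyond
// the hull; a convex g <= up+d pointwise exists iff the gcm of the upper
// band clears the lower band, and the gcm of shifted points is the shifted
// gcm.) Hence
//   dip = 0.5 * min_m max( L(m), R(m) ),
//   L(m) = max_{j<m} [ lo_j - gcm_{<=m}(up)(x_j) ]   (nondecreasing in m)
//   R(m) = max_{j>m} [ lcm_{>=m}(lo)(x_j) - up_j ]   (nonincreasing in m)
// and the minimum over m sits at the L/R crossing: binary search.

namespace {

// max_{j<m} ( lo_j - gcm(x, up on 1..m)(x_j) ), indices 0-based, m inclusive
double left_dev(const std::vector<double>& x,
                const std::vector<double>& lo,
                const std::vector<double>& up,
                int m) {
  std::vector<int> h; // lower convex hull of (x_j, up_j), j = 0..m
  h.reserve(m + 1);
  for (int j = 0; j <= m; ++j) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      // pop b if slope(b, j) <= slope(a, b)
      if ((up[j] - up[b]) * (x[b] - x[a]) <= (up[b] - up[a]) * (x[j] - x[b]))
        h.pop_back();
      else
        break;
    }
    h.push_back(j);
  }
  double dev = 0.0;
  for (size_t t = 0; t + 1 < h.size(); ++t) {
    int a = h[t], b = h[t + 1];
    double slope = (up[b] - up[a]) / (x[b] - x[a]);
    for (int j = a; j <= b && j < m; ++j) {
      double g = up[a] + slope * (x[j] - x[a]);
      if (lo[j] - g > dev) dev = lo[j] - g;
    }
  }
  if (h.size() == 1 && m > 0) { // degenerate (single hull point)
    for (int j = 0; j < m; ++j)
      if (lo[j] - up[h[0]] > dev) dev = lo[j] - up[h[0]];
  }
  return dev;
}

// mirror image: max_{j>m} ( lcm(x, lo on m..k-1)(x_j) - up_j )
double right_dev(const std::vector<double>& x,
                 const std::vector<double>& lo,
                 const std::vector<double>& up,
                 int m) {
  int k = (int)x.size();
  std::vector<int> h; // upper concave hull of (x_j, lo_j), j = m..k-1
  h.reserve(k - m);
  for (int j = m; j < k; ++j) {
    while (h.size() >= 2) {
      int a = h[h.size() - 2], b = h[h.size() - 1];
      if ((lo[j] - lo[b]) * (x[b] - x[a]) >= (lo[b] - lo[a]) * (x[j] - x[b]))
        h.pop_back();
      else
        break;
    }
    h.push_back(j);
  }
  double dev = 0.0;
  for (size_t t = 0; t + 1 < h.size(); ++t) {
    int a = h[t], b = h[t + 1];
    double slope = (lo[b] - lo[a]) / (x[b] - x[a]);
    for (int j = a; j <= b; ++j) {
      if (j <= m) continue;
      double g = lo[a] + slope * (x[j] - x[a]);
      if (g - up[j] > dev) dev = g - up[j];
    }
  }
  return dev;
}

double dip_sorted(const std::vector<double>& xs) {
  int n = (int)xs.size();
  if (n < 2) return 0.0;
  // collapse ties: lo = cumulative mass at x_j, up = mass just left of x_j
  std::vector<double> x, lo, up;
  x.reserve(n); lo.reserve(n); up.reserve(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && xs[j] == xs[i]) ++j;
    x.push_back(xs[i]);
    up.push_back((double)i / n);
    lo.push_back((double)j / n);
    i = j;
  }
  int k = (int)x.size();
  if (k == 1) return 0.0;
  // binary search the crossing of L (nondecreasing) and R (nonincreasing)
  int a = 0, b = k - 1;
  while (a < b) {
    int mid = (a + b) / 2;
    if (left_dev(x, lo, up, mid) < right_dev(x, lo, up, mid))
      a = mid + 1;
    else
      b = mid;
  }
  double best = R_PosInf;
  for (int m = std::max(0, a - 1); m <= std::min(k - 1, a + 1); ++m) {
    double d = std::max(left_dev(x, lo, up, m), right_dev(x, lo, up, m));
    if (d < best) best = d;
  }
  return 0.5 * std::max(0.0, best);
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  std::sort(xs.begin(), xs.end());
  return dip_sorted(xs);
}

// B dip statistics of uniform(0,1) samples of size n, using R's RNG
// (so set.seed() in R controls reproducibility)
// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int B) {
  NumericVector out(B);
  std::vector<double> xs(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) xs[i] = unif_rand();
    std::sort(xs.begin(), xs.end());
    out[b] = dip_sorted(xs);
  }
  return out;
}
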