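#include <Rcpp.h>
using namespace Rcpp;

// Duration-sensitive scanpath alignment (Scasim). Global alignment by
// dynamic programming; gap cost of a fixation is its duration, substitution
// cost of fixations a, b is
//   dur_a + dur_b - 2 * min(dur_a, dur_b) * modulator^d(a, b)
// with d(a, b) the angular distance in degrees between the two fixation
// positions (full atan formula from pixel distance and display geometry).

static inline double ang_dist(double dx, double dy,
                              double px_mm, double dist_mm) {
  double dpx = std::sqrt(dx * dx + dy * dy);
  return 2.0 * std::atan((dpx * px_mm) / (2.0 * dist_mm)) * 180.0 / M_PI;
}

// [[Rcpp::export]]
double scasim_pair_cpp(NumericVector x1, NumericVector y1, NumericVector d1,
                       NumericVector x2, NumericVector y2, NumericVector d2,
                       double modulator, double px_mm, double dist_mm) {
  int n = d1.size(), m = d2.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  prev[0] = 0.0;
  for (int j = 1; j <= m; ++j) prev[j] = prev[j - 1] + d2[j - 1];
  for (int i = 1; i <= n; ++i) {
    cur[0] = prev[0] + d1[i - 1];
    for (int j = 1; j <= m; ++j) {
      double d = ang_dist(x1[i - 1] - x2[j - 1], y1[i - 1] - y2[j - 1],
                          px_mm, dist_mm);
      double mn = std::min(d1[i - 1], d2[j - 1]);
      double sub = d1[i - 1] + d2[j - 1] -
        2.0 * mn * std::pow(modulator, d);
      double best = prev[j - 1] + sub;
      double up = prev[j] + d1[i - 1];
      double left = cur[j - 1] + d2[j - 1];
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
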