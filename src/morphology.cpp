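#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grayscale dilation / erosion with a spherical (ball) structuring
// function s(dx,dy) = sqrt(r^2 - dx^2 - dy^2) on the disc dx^2+dy^2 <= r^2.
// Out-of-bounds neighbours are ignored (the ball follows the border).
// closing = erode(dilate(img)) is the upper envelope traced by a ball of
// radius r rolling on top of the intensity surface.

static NumericMatrix ball_transform(const NumericMatrix& img, double radius,
                                    bool dilate) {
  const int H = img.nrow(), W = img.ncol();
  const int r = (int)std::floor(radius);
  // precompute structuring-function offsets
  std::vector<int> du, dv;
  std::vector<double> z;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= radius * radius) {
        du.push_back(a);
        dv.push_back(b);
        z.push_back(std::sqrt(radius * radius - d2));
      }
    }
  const int K = (int)du.size();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double best = dilate ? R_NegInf : R_PosInf;
      for (int k = 0; k < K; ++k) {
        int y = i + du[k], x = j + dv[k];
        if (y < 0 || y >= H || x < 0 || x >= W) continue;
        double v = dilate ? img(y, x) + z[k] : img(y, x) - z[k];
        if (dilate ? (v > best) : (v < best)) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_closing(NumericMatrix img, double radius) {
  return ball_transform(ball_transform(img, radius, true), radius, false);
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_opening(NumericMatrix img, double radius) {
  return ball_transform(ball_transform(img, radius, false), radius, true);
}

// Exact two-sided permutation p-value for the Spearman statistic: ranks of
// one variable are permuted exhaustively (std::next_permutation over the
// sorted multiset enumerates each distinct arrangement once; arrangements
// of a multiset are equiprobable under uniform permutation). Feasible for
// n <= 10 (10! = 3,628,800).

// [[Rcpp::export]]
double cpp_spearman_perm_p(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  if (n != ry.size()) stop("rank vectors differ in length");
  std::vector<double> x(rx.begin(), rx.end());
  std::vector<double> y(ry.begin(), ry.end());
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double s_obs = 0;
  for (int i = 0; i < n; ++i) s_obs += x[i] * y[i];
  const double centre = n * mx * my;
  const double t_obs = std::fabs(s_obs - centre) - 1e-9;
  std::sort(y.begin(), y.end());
  long long hits = 0, total = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) s += x[i] * y[i];
    if (std::fabs(s - centre) >= t_obs) ++hits;
    ++total;
  } while (std::next_permutation(y.begin(), y.end()));
  return (double)hits / (double)total;
}
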