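#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. f holds squared distances; result in d.
static void dt1d(const std::vector<double> &f, std::vector<double> &d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from every true pixel to the nearest false
// pixel. With outside_background = true (the default for foot masks),
// pixels outside the image count as false, so masks touching the border
// stay finite; with false, the outside is ignored (needed when measuring
// distance *to* a set, e.g. for dilation).
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(LogicalMatrix mask, bool outside_background = true) {
  const int H = mask.nrow(), W = mask.ncol();
  const int Hp = H + 2, Wp = W + 2; // 1-px pad
  const double INF = 1e18;
  std::vector<double> g(Hp * Wp);
  for (int j = 0; j < Wp; j++)
    for (int i = 0; i < Hp; i++) {
      bool in_img = (i > 0 && i <= H && j > 0 && j <= W);
      bool far = in_img ? mask(i - 1, j - 1) : !outside_background;
      g[j * Hp + i] = far ? INF : 0.0;
    }
  std::vector<double> f(std::max(Hp, Wp)), d(std::max(Hp, Wp));
  // transform along columns
  for (int j = 0; j < Wp; j++) {
    for (int i = 0; i < Hp; i++) f[i] = g[j * Hp + i];
    f.resize(Hp); d.resize(Hp);
    dt1d(f, d);
    for (int i = 0; i < Hp; i++) g[j * Hp + i] = d[i];
  }
  // then along rows
  NumericMatrix out(H, W);
  f.resize(Wp); d.resize(Wp);
  for (int i = 0; i < Hp; i++) {
    for (int j = 0; j < Wp; j++) f[j] = g[j * Hp + i];
    dt1d(f, d);
    if (i > 0 && i <= H)
      for (int j = 1; j <= W; j++) out(i - 1, j - 1) = d[j];
  }
  return out;
}

// Connected-component labelling by flood fill. connectivity: 4 or 8.
// Returns integer matrix, 0 = background, components numbered from 1 in
// row-major order of first occurrence.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  const int nn = (connectivity == 4) ? 4 : 8;
  // row-major scan: rows outer so labels follow the row-major convention
  for (int i = 0; i < H; i++)
    for (int j = 0; j < W; j++) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      next++;
      lab(i, j) = next;
      stack.push_back(i * W + j);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int r = p / W, c = p % W;
        for (int q = 0; q < nn; q++) {
          int r2 = r + dr[q], c2 = c + dc[q];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 * W + c2);
          }
        }
      }
    }
  return lab;
}
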