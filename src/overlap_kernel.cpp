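#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sliding mean / population sd (divide by w) for all window starts,
// via running sums. Negative variances from rounding are clamped at 0.
static void win_stats(const NumericVector& x, int w,
                      std::vector<double>& mu, std::vector<double>& sd) {
  int n = x.size();
  int K = n - w + 1;
  mu.assign(K, 0.0);
  sd.assign(K, 0.0);
  double s = 0.0, ss = 0.0;
  for (int i = 0; i < w; ++i) { s += x[i]; ss += x[i] * x[i]; }
  for (int k = 0; k < K; ++k) {
    if (k > 0) {
      s  += x[k + w - 1] - x[k - 1];
      ss += x[k + w - 1] * x[k + w - 1] - x[k - 1] * x[k - 1];
    }
    double m = s / w;
    double v = ss / w - m * m;
    if (v < 0) v = 0;
    mu[k] = m;
    sd[k] = std::sqrt(v);
  }
}

// [[Rcpp::export]]
List cpp_sliding_mean_std(NumericVector x, int w) {
  if (w < 1 || x.size() < w) stop("series shorter than window");
  std::vector<double> mu, sd;
  win_stats(x, w, mu, sd);
  return List::create(_["mean"] = NumericVector(mu.begin(), mu.end()),
                      _["std"]  = NumericVector(sd.begin(), sd.end()));
}

// Maximum sliding-window Pearson correlation between all window pairs
// (l1 on ref, l2 on query), windows of width w. Dot products are updated
// incrementally along alignment diagonals (l1 - l2 constant), so every
// placement costs O(1) after an O(w) diagonal start. Windows with
// sd <= sd_tol on either side are excluded. Ties (within 1e-12) break to
// the smallest l2, then smallest l1. Returns 0-based l1, l2.
// [[Rcpp::export]]
List cpp_best_window_pcc(NumericVector ref, NumericVector query, int w,
                         double sd_tol = 1e-9) {
  int n1 = ref.size(), n2 = query.size();
  if (w < 2) stop("window width must be >= 2");
  if (n1 < w || n2 < w) stop("barcode shorter than window");
  int K1 = n1 - w + 1, K2 = n2 - w + 1;
  std::vector<double> mu1, sd1, mu2, sd2;
  win_stats(ref, w, mu1, sd1);
  win_stats(query, w, mu2, sd2);
  // precompute w*mu and 1/(sqrt(w)*sd); excluded windows get inv = 0 so
  // their score becomes <= 0 minus a large offset and never wins
  const double BIG = 4.0;  // any PCC lies in [-1, 1]
  std::vector<double> wmu1(K1), inv1(K1), wmu2(K2), inv2(K2);
  std::vector<double> pen1(K1), pen2(K2);
  double sw = std::sqrt((double) w);
  for (int k = 0; k < K1; ++k) {
    wmu1[k] = w * mu1[k];
    bool ok = sd1[k] > sd_tol;
    inv1[k] = ok ? 1.0 / (sw * sd1[k]) : 0.0;
    pen1[k] = ok ? 0.0 : BIG;
  }
  for (int k = 0; k < K2; ++k) {
    wmu2[k] = w * mu2[k];
    bool ok = sd2[k] > sd_tol;
    inv2[k] = ok ? 1.0 / (sw * sd2[k]) : 0.0;
    pen2[k] = ok ? 0.0 : BIG;
  }
  const double *x = REAL(ref), *y = REAL(query);
  const double eps = 1e-12;
  double best = R_NegInf;
  int bl1 = -1, bl2 = -1;
  for (int s = -(K2 - 1); s <= K1 - 1; ++s) {
    int l1 = s > 0 ? s : 0;
    int l2 = l1 - s;
    int steps = std::min(K1 - l1, K2 - l2);  // placements on this diagonal
    double dot = 0.0;
    const double *xs = x + l1, *ys = y + l2;
    for (int k = 0; k < w; ++k) dot += xs[k] * ys[k];
    for (int t = 0; t < steps; ++t) {
      double c = (dot - wmu1[l1] * mu2[l2]) * inv1[l1] * inv2[l2]
                 - pen1[l1] - pen2[l2];
      if (c > best - eps) {
        if (c > best + eps ||
            (bl2 < 0 || l2 < bl2 || (l2 == bl2 && l1 < bl1))) {
          if (c > best) best = c;
          bl1 = l1; bl2 = l2;
        }
      }
      if (t + 1 < steps) {
        dot += x[l1 + w] * y[l2 + w] - x[l1] * y[l2];
        ++l1; ++l2;
      }
    }
  }
  if (bl1 < 0 || best < -1.5)  // only variance-excluded placements found
    return List::create(_["C"] = NA_REAL, _["l1"] = NA_INTEGER, _["l2"] = NA_INTEGER);
  return List::create(_["C"] = best, _["l1"] = bl1, _["l2"] = bl2);
}

// Pearson correlation of x[i] vs y[i] over given 0-based index pairs.
// [[Rcpp::export]]
double cpp_pcc_at(NumericVector x, NumericVector y,
                  IntegerVector ix, IntegerVector iy) {
  int n = ix.size();
  if (n != iy.size() || n < 2) return NA_REAL;
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int k = 0; k < n; ++k) {
    double a = x[ix[k]], b = y[iy[k]];
    sx += a; sy += b; sxx += a * a; syy += b * b; sxy += a * b;
  }
  double mx = sx / n, my = sy / n;
  double vx = sxx / n - mx * mx, vy = syy / n - my * my;
  if (vx <= 0 || vy <= 0) return NA_REAL;
  return (sxy / n - mx * my) / std::sqrt(vx * vy);
}
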