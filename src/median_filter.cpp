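#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact square median filter of radius r with replicated (clamped) edges.
// Values are untouched apart from the median selection, so the filter is
// the identity on constant regions larger than the kernel.
// [[Rcpp::export(name = ".medianFilterSqCpp")]]
NumericMatrix medianFilterSqCpp(NumericMatrix m, int r) {
  const int h = m.nrow(), w = m.ncol();
  if (r <= 0) return clone(m);
  const int k = (2 * r + 1) * (2 * r + 1);
  NumericMatrix out(h, w);
  if (r == 1) {
    // 3x3 case: branch-light median-of-9 exchange network per pixel
    const double *src = m.begin();
    double *dst = out.begin();
    auto sw = [](double &a, double &b) {
      double lo = std::min(a, b), hi = std::max(a, b);
      a = lo; b = hi;
    };
    for (int j = 0; j < w; ++j) {
      const int jm = (j > 0 ? j - 1 : 0) * h, j0 = j * h,
                jp = (j < w - 1 ? j + 1 : j) * h;
      for (int i = 0; i < h; ++i) {
        const int im = i > 0 ? i - 1 : 0, ip = i < h - 1 ? i + 1 : i;
        double p0 = src[jm + im], p1 = src[jm + i], p2 = src[jm + ip],
               p3 = src[j0 + im], p4 = src[j0 + i], p5 = src[j0 + ip],
               p6 = src[jp + im], p7 = src[jp + i], p8 = src[jp + ip];
        sw(p1, p2); sw(p4, p5); sw(p7, p8); sw(p0, p1); sw(p3, p4);
        sw(p6, p7); sw(p1, p2); sw(p4, p5); sw(p7, p8); sw(p0, p3);
        sw(p5, p8); sw(p4, p7); sw(p3, p6); sw(p1, p4); sw(p2, p5);
        sw(p4, p7); sw(p4, p2); sw(p6, p4); sw(p4, p2);
        dst[j0 + i] = p4;
      }
    }
    return out;
  }
  std::vector<double> buf(k);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      int n = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int cj = std::min(std::max(j + dj, 0), w - 1);
        for (int di = -r; di <= r; ++di) {
          int ci = std::min(std::max(i + di, 0), h - 1);
          buf[n++] = m(ci, cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

// Row-wise argmax with ties to the lowest column index.
// [[Rcpp::export(name = ".rowArgmaxCpp")]]
IntegerVector rowArgmaxCpp(NumericMatrix x) {
  const int n = x.nrow(), k = x.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int best = 0;
    double bv = x(i, 0);
    for (int j = 1; j < k; ++j)
      if (x(i, j) > bv) { bv = x(i, j); best = j; }
    out[i] = best + 1;
  }
  return out;
}
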