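#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Grayscale erosion/dilation with a (possibly non-flat) structuring function.
// The structuring element is given as parallel vectors of row/col offsets and
// heights. Out-of-bounds samples are ignored (treated as +Inf for erosion,
// -Inf for dilation), the usual border convention for background estimation.

// [[Rcpp::export]]
NumericMatrix gray_erode_cpp(const NumericMatrix& img,
                             const IntegerVector& off_r,
                             const IntegerVector& off_c,
                             const NumericVector& height) {
  const int H = img.nrow(), W = img.ncol(), K = off_r.size();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double m = std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        int rr = r + off_r[k], cc = c + off_c[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        double v = img(rr, cc) - height[k];
        if (v < m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix gray_dilate_cpp(const NumericMatrix& img,
                              const IntegerVector& off_r,
                              const IntegerVector& off_c,
                              const NumericVector& height) {
  const int H = img.nrow(), W = img.ncol(), K = off_r.size();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double m = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        int rr = r - off_r[k], cc = c - off_c[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        double v = img(rr, cc) + height[k];
        if (v > m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}
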