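#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dependent multivariate DTW: one warping path over the vector-valued
// series, local cost = Euclidean distance between feature vectors
// (rows of a and b), no band constraint. Returns the cumulative cost of
// the optimal alignment.
// [[Rcpp::export]]
double dtw_dist_cpp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow(), d = a.ncol();
  if (d != b.ncol()) stop("feature dimension mismatch");
  if (n == 0 || m == 0) stop("empty series");
  std::vector<double> prev(m), curr(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = a(i, k) - b(j, k);
        c += diff * diff;
      }
      c = std::sqrt(c);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else if (i == 0) best = curr[j - 1];
      else if (j == 0) best = prev[j];
      else best = std::min(prev[j], std::min(curr[j - 1], prev[j - 1]));
      curr[j] = c + best;
    }
    std::swap(prev, curr);
  }
  return prev[m - 1];
}

// Full pairwise DTW distance matrix over a list of W x d feature matrices.
// [[Rcpp::export]]
NumericMatrix dtw_matrix_cpp(List series) {
  const int n = series.size();
  NumericMatrix D(n, n);
  std::vector<NumericMatrix> mats;
  mats.reserve(n);
  for (int i = 0; i < n; ++i) mats.push_back(as<NumericMatrix>(series[i]));
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = dtw_dist_cpp(mats[i], mats[j]);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// 3x3 median filter with reflected borders, applied to one 2D frame.
// [[Rcpp::export]]
NumericMatrix median3x3_cpp(NumericMatrix img) {
  const int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  double w[9];
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) {
      int k = 0;
      for (int dy = -1; dy <= 1; ++dy) {
        int yy = y + dy;
        if (yy < 0) yy = -yy;              // reflect
        if (yy >= ny) yy = 2 * ny - 2 - yy;
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx;
          if (xx < 0) xx = -xx;
          if (xx >= nx) xx = 2 * nx - 2 - xx;
          w[k++] = img(yy, xx);
        }
      }
      std::nth_element(w, w + 4, w + 9);
      out(y, x) = w[4];
    }
  }
  return out;
}
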