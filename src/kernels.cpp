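#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Distance between rows i of A and j of B. metric: 0 = Chebyshev, 1 = Euclidean.
static inline double row_dist(const NumericMatrix &A, int i,
                              const NumericMatrix &B, int j, int metric) {
  const int d = A.ncol();
  if (metric == 0) {
    double mx = 0.0;
    for (int k = 0; k < d; ++k) {
      double v = std::fabs(A(i, k) - B(j, k));
      if (v > mx) mx = v;
    }
    return mx;
  }
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double v = A(i, k) - B(j, k);
    s += v * v;
  }
  return std::sqrt(s);
}

// Count unordered pairs i < j (rows of X, restricted to the first nrow_use
// rows) whose distance is <= r.
// [[Rcpp::export]]
double pair_count_within(NumericMatrix X, double r, int metric, int nrow_use) {
  const int n = (nrow_use > 0 && nrow_use <= X.nrow()) ? nrow_use : X.nrow();
  double cnt = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (row_dist(X, i, X, j, metric) <= r) cnt += 1.0;
  return cnt;
}

// Per-row neighbour counts within the same matrix; self-match optionally
// included (approximate-entropy convention).
// [[Rcpp::export]]
NumericVector row_neighbour_counts(NumericMatrix X, double r, int metric,
                                   bool include_self) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = include_self ? 1.0 : 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (row_dist(X, i, X, j, metric) <= r) {
        out[i] += 1.0;
        out[j] += 1.0;
      }
  return out;
}

// Per-row counts of rows of Y within r of each row of X (cross matching; all
// ordered pairs, no self-match concept).
// [[Rcpp::export]]
NumericVector cross_neighbour_counts(NumericMatrix X, NumericMatrix Y,
                                     double r, int metric) {
  const int nx = X.nrow(), ny = Y.nrow();
  NumericVector out(nx);
  for (int i = 0; i < nx; ++i) {
    double c = 0.0;
    for (int j = 0; j < ny; ++j)
      if (row_dist(X, i, Y, j, metric) <= r) c += 1.0;
    out[i] = c;
  }
  return out;
}

// Sum of fuzzy memberships mu(d) over unordered pairs i < j of the first
// nrow_use rows. type: 0 exponential exp(-d^p / r), 1 gaussian
// exp(-(d/r)^2 / 2), 2 triangular max(1 - d/r, 0),
// 3 sigmoid 1 / (1 + exp((d - p) / r)).
static inline double membership(double d, double r, double p, int type) {
  switch (type) {
  case 0: return std::exp(-std::pow(d, p) / r);
  case 1: return std::exp(-0.5 * (d / r) * (d / r));
  case 2: return (d < r) ? (1.0 - d / r) : 0.0;
  default: return 1.0 / (1.0 + std::exp((d - p) / r));
  }
}

// [[Rcpp::export]]
double fuzzy_pair_sum(NumericMatrix X, double r, double p, int type,
                      int metric, int nrow_use) {
  const int n = (nrow_use > 0 && nrow_use <= X.nrow()) ? nrow_use : X.nrow();
  double s = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      s += membership(row_dist(X, i, X, j, metric), r, p, type);
  return s;
}

// [[Rcpp::export]]
double fuzzy_cross_sum(NumericMatrix X, NumericMatrix Y, double r, double p,
                       int type, int metric) {
  double s = 0.0;
  for (int i = 0; i < X.nrow(); ++i)
    for (int j = 0; j < Y.nrow(); ++j)
      s += membership(row_dist(X, i, Y, j, metric), r, p, type);
  return s;
}

// All unordered pairwise distances among the first nrow_use rows.
// [[Rcpp::export]]
NumericVector pairwise_dists(NumericMatrix X, int metric, int nrow_use) {
  const int n = (nrow_use > 0 && nrow_use <= X.nrow()) ? nrow_use : X.nrow();
  const R_xlen_t m = (R_xlen_t)n * (n - 1) / 2;
  NumericVector out(m);
  R_xlen_t k = 0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      out[k++] = row_dist(X, i, X, j, metric);
  return out;
}

// All ordered cross distances between rows of X and rows of Y.
// [[Rcpp::export]]
NumericVector cross_dists(NumericMatrix X, NumericMatrix Y, int metric) {
  const int nx = X.nrow(), ny = Y.nrow();
  NumericVector out((R_xlen_t)nx * ny);
  R_xlen_t k = 0;
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j)
      out[k++] = row_dist(X, i, Y, j, metric);
  return out;
}

// Count cross pairs within r without materialising the distance vector.
// [[Rcpp::export]]
double cross_count_within(NumericMatrix X, NumericMatrix Y, double r,
                          int metric) {
  double cnt = 0.0;
  for (int i = 0; i < X.nrow(); ++i)
    for (int j = 0; j < Y.nrow(); ++j)
      if (row_dist(X, i, Y, j, metric) <= r) cnt += 1.0;
  return cnt;
}
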