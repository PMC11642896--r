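// Pairwise-template entropy estimators (O(n^2) kernels kept in C++).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double chebyshev(const NumericVector& x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double v = std::fabs(x[i + k] - x[j + k]);
    if (v > d) d = v;
  }
  return d;
}

// Sample entropy, m template length, r tolerance; self-matches excluded.
// [[Rcpp::export]]
double cpp_sampen(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) return NA_REAL;
  long A = 0, B = 0;
  int nm = n - m;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      if (chebyshev(x, i, j, m) <= r) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
      }
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

// Approximate entropy (self-matches included).
// [[Rcpp::export]]
double cpp_apen(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) return NA_REAL;
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int N = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      int cnt = 0;
      for (int j = 0; j < N; ++j)
        if (chebyshev(x, i, j, mm) <= r) ++cnt;
      acc += std::log((double)cnt / (double)N);
    }
    phi[s] = acc / N;
  }
  return phi[0] - phi[1];
}

// Fuzzy entropy: exponential membership exp(-(d/r)^2) on mean-centred
// templates.
// [[Rcpp::export]]
double cpp_fuzzyen(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) return NA_REAL;
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int N = n - mm;
    std::vector<double> mu(N);
    for (int i = 0; i < N; ++i) {
      double acc = 0.0;
      for (int k = 0; k < mm; ++k) acc += x[i + k];
      mu[i] = acc / mm;
    }
    double tot = 0.0;
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double v = std::fabs((x[i + k] - mu[i]) - (x[j + k] - mu[j]));
          if (v > d) d = v;
        }
        tot += std::exp(-(d * d) / (r * r));
      }
    }
    phi[s] = tot / ((double)N * (N - 1) / 2.0);
  }
  if (phi[0] <= 0 || phi[1] <= 0) return NA_REAL;
  return std::log(phi[0] / phi[1]);
}

// Cross-sample entropy between two standardized series.
// [[Rcpp::export]]
double cpp_cross_sampen(NumericVector x, NumericVector y, int m, double r) {
  int n = std::min(x.size(), y.size());
  if (n < m + 2) return NA_REAL;
  long A = 0, B = 0;
  int nm = n - m;
  for (int i = 0; i < nm; ++i) {
    for (int j = 0; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double v = std::fabs(x[i + k] - y[j + k]);
        if (v > d) d = v;
      }
      if (d <= r) {
        ++B;
        if (std::fabs(x[i + m] - y[j + m]) <= r) ++A;
      }
    }
  }
  if (A == 0 || B == 0) return NA_REAL;
  return -std::log((double)A / (double)B);
}

// Cross-approximate entropy.
// [[Rcpp::export]]
double cpp_cross_apen(NumericVector x, NumericVector y, int m, double r) {
  int n = std::min(x.size(), y.size());
  if (n < m + 2) return NA_REAL;
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    int N = n - mm + 1;
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      int cnt = 0;
      for (int j = 0; j < N; ++j) {
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double v = std::fabs(x[i + k] - y[j + k]);
          if (v > d) d = v;
        }
        if (d <= r) ++cnt;
      }
      if (cnt == 0) return NA_REAL;
      acc += std::log((double)cnt / (double)N);
    }
    phi[s] = acc / N;
  }
  return phi[0] - phi[1];
}
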