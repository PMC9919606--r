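#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// C-SVM dual solver (SMO with first-order working-set selection, as in
// LIBSVM).  The kernel matrix is precomputed, which is fine for the few
// thousand training rows this pipeline produces.

namespace {

inline double kern(const NumericMatrix &X, int i, int j, bool rbf,
                   double gamma) {
  int p = X.ncol();
  double acc = 0.0;
  if (rbf) {
    for (int k = 0; k < p; ++k) {
      double d = X(i, k) - X(j, k);
      acc += d * d;
    }
    return std::exp(-gamma * acc);
  }
  for (int k = 0; k < p; ++k) acc += X(i, k) * X(j, k);
  return acc;
}

} // namespace

// y in {-1, +1}
// [[Rcpp::export(name = ".svm_fit")]]
List svm_fit(NumericMatrix X, NumericVector y, double C, bool rbf,
             double gamma, double tol, int max_iter) {
  int n = X.nrow();
  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double v = kern(X, i, j, rbf, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  long long iter = 0, cap = (max_iter > 0) ? max_iter : 10000000LL;

  while (iter++ < cap) {
    // working pair: i maximizes -y G over I_up, j minimizes over I_low
    int i = -1, j = -1;
    double m = -1e300, M = 1e300;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;

    double eta = K[(size_t)i * n + i] + K[(size_t)j * n + j] -
                 2.0 * K[(size_t)i * n + j];
    if (eta <= 0) eta = 1e-12;
    double delta = (m - M) / eta;  // step along (+y_i e_i, -y_j e_j)

    // clip so both alphas stay in [0, C]
    double lim_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    double lim_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    delta = std::min(delta, std::min(lim_i, lim_j));
    if (delta <= 0) break;

    alpha[i] += y[i] * delta;
    alpha[j] -= y[j] * delta;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * delta * (K[(size_t)t * n + i] - K[(size_t)t * n + j]);
  }

  // intercept from free support vectors, fall back to the KKT midpoint
  double bsum = 0.0; int nfree = 0;
  double m = -1e300, M = 1e300;
  for (int t = 0; t < n; ++t) {
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    double v = -y[t] * G[t];
    if (up && v > m) m = v;
    if (lo && v < M) M = v;
    if (alpha[t] > 0 && alpha[t] < C) { bsum += v; ++nfree; }
  }
  double b = nfree > 0 ? bsum / nfree : 0.5 * (m + M);

  std::vector<int> sv;
  for (int t = 0; t < n; ++t) if (alpha[t] > 1e-12) sv.push_back(t);
  int ns = sv.size();
  NumericMatrix Xs(ns, X.ncol());
  NumericVector coef(ns);
  for (int s = 0; s < ns; ++s) {
    coef[s] = alpha[sv[s]] * y[sv[s]];
    for (int k = 0; k < X.ncol(); ++k) Xs(s, k) = X(sv[s], k);
  }
  return List::create(_["sv"] = Xs, _["coef"] = coef, _["b"] = b,
                      _["iterations"] = (double)iter);
}

// [[Rcpp::export(name = ".svm_decision")]]
NumericVector svm_decision(NumericMatrix Xs, NumericVector coef, double b,
                           NumericMatrix X, bool rbf, double gamma) {
  int n = X.nrow(), ns = Xs.nrow(), p = X.ncol();
  NumericVector f(n);
  for (int i = 0; i < n; ++i) {
    double acc = b;
    for (int s = 0; s < ns; ++s) {
      double k;
      if (rbf) {
        double d2 = 0.0;
        for (int t = 0; t < p; ++t) {
          double d = X(i, t) - Xs(s, t);
          d2 += d * d;
        }
        k = std::exp(-gamma * d2);
      } else {
        k = 0.0;
        for (int t = 0; t < p; ++t) k += X(i, t) * Xs(s, t);
      }
      acc += coef[s] * k;
    }
    f[i] = acc;
  }
  return f;
}
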