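#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// RBF-kernel C-SVC trained by sequential minimal optimization with
// maximal-violating-pair working-set selection.
//
// Dual: min 1/2 a'Qa - e'a, 0 <= a_i <= C, y'a = 0, Q_ij = y_i y_j K(x_i,x_j).
// We track f_i = sum_t a_t y_t K(t,i); the violating-pair criterion uses
// y_i - f_i, and at optimality m = max_{I_up}(y-f) <= M = min_{I_low}(y-f).

static double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  const int p = X.ncol();
  for (int k = 0; k < p; ++k) {
    const double d = X(i, k) - X(j, k);
    s += d * d;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List smo_train_cpp(NumericMatrix X, IntegerVector y, double C, double gamma,
                   double tol = 1e-3, int max_iter = 1000000) {
  const int n = X.nrow();
  if (n < 2) stop("need at least 2 training rows");
  if (C <= 0.0 || gamma <= 0.0) stop("C and gamma must be positive");

  // precompute the kernel matrix; n is small for peptide benchmarks
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    K(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) K(i, j) = K(j, i) = rbf(X, i, j, gamma);
  }

  std::vector<double> alpha(n, 0.0), f(n, 0.0);
  double m_up = 0.0, m_low = 0.0;
  int iter = 0;
  const double beps = 1e-12 * C;  // bound tolerance for I_up/I_low membership

  for (iter = 0; iter < max_iter; ++iter) {
    // working-set selection: maximal violating pair
    int i1 = -1, i2 = -1;
    m_up = -HUGE_VAL;
    m_low = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      const double v = y[t] - f[t];
      const bool up  = (y[t] ==  1 && alpha[t] < C - beps) || (y[t] == -1 && alpha[t] > beps);
      const bool low = (y[t] ==  1 && alpha[t] > beps) || (y[t] == -1 && alpha[t] < C - beps);
      if (up && v > m_up) { m_up = v; i1 = t; }
      if (low && v < m_low) { m_low = v; i2 = t; }
    }
    if (i1 < 0 || i2 < 0 || m_up - m_low < tol) break;

    const double y1 = y[i1], y2 = y[i2];
    const double a1 = alpha[i1], a2 = alpha[i2];
    const double s = y1 * y2;
    double L, H;
    if (s < 0) { L = std::max(0.0, a2 - a1); H = std::min(C, C + a2 - a1); }
    else       { L = std::max(0.0, a1 + a2 - C); H = std::min(C, a1 + a2); }

    double eta = K(i1, i1) + K(i2, i2) - 2.0 * K(i1, i2);
    if (eta < 1e-12) eta = 1e-12;
    const double E1 = f[i1] - y1, E2 = f[i2] - y2;
    double a2new = a2 + y2 * (E1 - E2) / eta;
    if (a2new < L) a2new = L; else if (a2new > H) a2new = H;
    double a1new = a1 + s * (a2 - a2new);
    // snap to exact bounds so rounding error cannot strand an alpha just
    // inside a bound and stall the working-set selection
    if (a1new < beps) a1new = 0.0; else if (a1new > C - beps) a1new = C;
    if (a2new < beps) a2new = 0.0; else if (a2new > C - beps) a2new = C;
    if (std::fabs(a2new - a2) < 1e-14 && std::fabs(a1new - a1) < 1e-14) break;

    const double d1 = (a1new - a1) * y1, d2 = (a2new - a2) * y2;
    for (int t = 0; t < n; ++t) f[t] += d1 * K(i1, t) + d2 * K(i2, t);
    alpha[i1] = a1new;
    alpha[i2] = a2new;
  }

  // intercept: average of y - f over free support vectors, else midpoint of
  // the bound interval from the final selection sweep
  double b = 0.0;
  int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-10 && alpha[t] < C - 1e-10) { b += y[t] - f[t]; ++nfree; }
  }
  if (nfree > 0) b /= nfree;
  else b = (m_up + m_low) / 2.0;

  LogicalVector sv(n);
  int nsv = 0;
  for (int t = 0; t < n; ++t) { sv[t] = alpha[t] > 1e-10; if (sv[t]) ++nsv; }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iter"] = iter, _["n_sv"] = nsv,
                      _["sv"] = sv);
}

// decision values f(x) = sum_i alpha_i y_i K(x_i, x) + b for new rows
// [[Rcpp::export]]
NumericVector smo_decision_cpp(NumericMatrix Xtrain, IntegerVector y,
                               NumericVector alpha, double b, double gamma,
                               NumericMatrix Xnew) {
  const int n = Xtrain.nrow(), m = Xnew.nrow(), p = Xtrain.ncol();
  if (Xnew.ncol() != p) stop("feature dimension mismatch");
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double acc = b;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] <= 0.0) continue;
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        const double d = Xtrain(i, k) - Xnew(j, k);
        s += d * d;
      }
      acc += alpha[i] * y[i] * std::exp(-gamma * s);
    }
    out[j] = acc;
  }
  return out;
}
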