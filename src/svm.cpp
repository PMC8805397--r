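#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// C-SVC with RBF kernel solved by SMO with maximal-violating-pair working
// set selection (the classic LIBSVM WSS1 rule). The kernel matrix is
// precomputed, which caps practical problem size at a few thousand rows --
// ample for the hard-instance probe this package uses it for.

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  for (int k = 0; k < X.ncol(); ++k) { double d = X(i, k) - X(j, k); s += d * d; }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List svm_smo(NumericMatrix X, NumericVector y, double C, double gamma,
             double eps, int max_iter) {
  int n = X.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);   // G = grad of dual = Q a - e
  std::vector<std::vector<double> > Q(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double q = y[i] * y[j] * rbf(X, i, j, gamma);
      Q[i][j] = q; Q[j][i] = q;
    }

  int iter = 0;
  while (iter++ < max_iter) {
    // select maximal violating pair
    double gmax = -1e300, gmin = 1e300; int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    // two-variable subproblem on (i, j)
    double quad = Q[i][i] + Q[j][j] - 2.0 * y[i] * y[j] * Q[i][j];
    if (quad <= 0) quad = 1e-12;
    double delta = (gmax - gmin) / quad;
    double ai = alpha[i], aj = alpha[j];
    alpha[i] += y[i] * delta;
    alpha[j] -= y[j] * delta;

    // clip to the feasible box preserving y^T alpha
    double sum = y[i] * ai + y[j] * aj;
    if (alpha[i] < 0) alpha[i] = 0;
    if (alpha[i] > C) alpha[i] = C;
    alpha[j] = y[j] * (sum - y[i] * alpha[i]);
    if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = y[i] * sum; }
    if (alpha[j] > C) { alpha[j] = C; alpha[i] = y[i] * (sum - y[j] * C); }

    double di = alpha[i] - ai, dj = alpha[j] - aj;
    for (int t = 0; t < n; ++t) G[t] += Q[t][i] * di + Q[t][j] * dj;
  }

  // intercept: average over free SVs, else midpoint of bounds
  double rho_sum = 0.0; int rho_n = 0;
  double ub = 1e300, lb = -1e300;
  for (int t = 0; t < n; ++t) {
    double yg = y[t] * G[t];
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { rho_sum += yg; ++rho_n; }
    if (up) ub = std::min(ub, yg);
    if (lo) lb = std::max(lb, yg);
  }
  double rho = rho_n > 0 ? rho_sum / rho_n : 0.5 * (ub + lb);

  std::vector<int> sv; std::vector<double> coef;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-12) { sv.push_back(t + 1); coef.push_back(alpha[t] * y[t]); }
  return List::create(_["sv_index"] = wrap(sv), _["coef"] = wrap(coef),
                      _["rho"] = rho, _["iterations"] = iter);
}

// [[Rcpp::export]]
NumericVector svm_decision(NumericMatrix SV, NumericVector coef, double rho,
                           double gamma, NumericMatrix X) {
  int n = X.nrow(), m = SV.nrow(), p = X.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) { double d = X(i, k) - SV(j, k); s += d * d; }
      acc += coef[j] * std::exp(-gamma * s);
    }
    out[i] = acc - rho;
  }
  return out;
}
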