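// Dual SVM solver: sequential minimal optimization with maximal-violating-
// pair working-set selection, operating on a precomputed kernel matrix.
// Binary subsets in this problem are a few hundred documents, so the full
// kernel matrix is small; the solver follows the standard C-SVC dual
//   min 1/2 a' Q a - e' a,  0 <= a <= C,  y' a = 0,  Q_ij = y_i y_j K_ij.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double eps = 1e-4, int max_iter = 200000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("kernel matrix must be square and match y");
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  bool converged = false;
  const double tau = 1e-12;

  while (iter < max_iter) {
    // working-set selection: maximal violating pair
    double gmax = -1e300, gmin = 1e300;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && v > gmax) { gmax = v; i = t; }
      if (in_low && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) { converged = true; break; }

    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = tau;
    double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    double d_i = y[i] * (alpha[i] - old_ai);
    double d_j = y[j] * (alpha[j] - old_aj);
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (K(t, i) * d_i + K(t, j) * d_j);
    ++iter;
  }

  // intercept: average of -y_t G_t over free support vectors, else the
  // midpoint of the feasibility bounds
  double b = 0.0; int n_free = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > tau && alpha[t] < C - tau) { b += -y[t] * G[t]; ++n_free; }
  }
  if (n_free > 0) {
    b /= n_free;
  } else {
    double ub = 1e300, lb = -1e300;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool in_up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && v > lb) lb = v;
      if (in_low && v < ub) ub = v;
    }
    b = (lb + ub) / 2.0;
  }

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iterations"] = iter,
                      _["converged"] = converged);
}
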