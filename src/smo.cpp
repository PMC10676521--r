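#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVC dual with a precomputed
// kernel matrix (maximal-violating-pair working-set selection, the classic
// LIBSVM stopping rule):
//   min_a  1/2 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,  Q_ij = y_i y_j K_ij
// Deterministic: ties resolve to the lowest index.
// [[Rcpp::export(name = ".smoSolve")]]
List smoSolve(NumericMatrix K, NumericVector y, double C,
              double tol = 1e-3, int maxIter = 500000) {
  const int n = K.nrow();
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int iter = 0;
  bool converged = false;
  while (iter < maxIter) {
    // select i: max -y_t G_t over I_up, j: min -y_t G_t over I_low
    int i = -1, j = -1;
    double gmax = -DBL_MAX, gmin = DBL_MAX;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < tol) { converged = true; break; }

    // analytic update of the (i, j) pair
    // curvature along the feasible direction (u_i, u_j) = (y_i, -y_j):
    // u' Q u = K_ii + K_jj - 2 K_ij for any label combination
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad <= 0) quad = 1e-12;
    double ai = alpha[i], aj = alpha[j];
    double delta = (gmax - gmin) / quad;  // = (-y_i G_i + y_j G_j)/quad
    double newAi = ai + y[i] * delta;
    double newAj = aj - y[j] * delta;

    // clip to the feasible segment (keep y'a = 0)
    double s = y[i] * ai + y[j] * aj;
    if (newAi < 0) newAi = 0;
    if (newAi > C) newAi = C;
    newAj = y[j] * (s - y[i] * newAi);
    if (newAj < 0) { newAj = 0; newAi = y[i] * (s - y[j] * newAj); }
    if (newAj > C) { newAj = C; newAi = y[i] * (s - y[j] * newAj); }
    if (newAi < 0) newAi = 0;
    if (newAi > C) newAi = C;

    double dAi = newAi - ai, dAj = newAj - aj;
    if (std::fabs(dAi) < 1e-14 && std::fabs(dAj) < 1e-14) { converged = true; break; }
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(i, t) * dAi + y[j] * K(j, t) * dAj);
    alpha[i] = newAi;
    alpha[j] = newAj;
    ++iter;
  }

  // intercept b: average of y_t - sum a_s y_s K_st over free vectors,
  // which equals -y_t G_t; fall back to the midpoint of the bounds
  double bSum = 0; int nFree = 0;
  double ub = DBL_MAX, lb = -DBL_MAX;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (alpha[t] > 1e-12 && alpha[t] < C - 1e-12) { bSum += v; ++nFree; }
    if (up && v < ub) ub = v;
    if (lo && v > lb) lb = v;
  }
  double b = nFree > 0 ? bSum / nFree : (ub + lb) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iter"] = iter,
                      _["converged"] = converged);
}
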