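#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM
// (Hsieh et al., ICML 2008) with the liblinear shrinking heuristic -- the
// algorithm behind liblinear / scikit-learn's LinearSVC. The bias is handled
// as an additional always-one feature that is itself regularized (liblinear's
// -B 1 convention).
//
// Primal:  min_w 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w' x_i)
// Dual:    min_a 0.5 a'Qa - e'a,  0 <= a_i <= C,  Q_ij = y_i y_j x_i'x_j
//
// Uses R's RNG for the per-sweep permutation, so results are reproducible
// under set.seed(). Returns c(w, b) of length p + 1.
// [[Rcpp::export(name = ".linsvmDcd")]]
NumericVector linsvm_dcd(const NumericMatrix& X, const NumericVector& y,
                         double C, int max_sweeps = 1000, double tol = 1e-4) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (!(C > 0)) stop("C must be positive");

  // row-major copy for cache-friendly per-sample dot products
  std::vector<double> Xr(static_cast<size_t>(n) * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) Xr[static_cast<size_t>(i) * p + j] = X(i, j);

  std::vector<double> w(p + 1, 0.0), alpha(n, 0.0), qii(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &Xr[static_cast<size_t>(i) * p];
    double s = 1.0;  // bias feature
    for (int j = 0; j < p; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int active = n;
  const double inf = std::numeric_limits<double>::infinity();
  double pgmax_old = inf, pgmin_old = -inf;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    // Fisher-Yates permutation of the active set, driven by R's RNG
    for (int i = active - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double pgmax = -inf, pgmin = inf;
    for (int k = 0; k < active; ++k) {
      const int i = idx[k];
      const double* xi = &Xr[static_cast<size_t>(i) * p];
      double wx = w[p];
      for (int j = 0; j < p; ++j) wx += w[j] * xi[j];
      const double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) {
        if (G > pgmax_old) {  // shrink this variable for the rest of the pass
          --active;
          std::swap(idx[k], idx[active]);
          --k;
          continue;
        }
        if (G >= 0.0) PG = 0.0;
      } else if (alpha[i] >= C) {
        if (G < pgmin_old) {
          --active;
          std::swap(idx[k], idx[active]);
          --k;
          continue;
        }
        if (G <= 0.0) PG = 0.0;
      }
      if (PG > pgmax) pgmax = PG;
      if (PG < pgmin) pgmin = PG;
      if (std::abs(PG) > 1e-12) {
        const double old = alpha[i];
        double a = old - G / qii[i];
        if (a < 0.0) a = 0.0; else if (a > C) a = C;
        alpha[i] = a;
        const double d = (a - old) * y[i];
        if (d != 0.0) {
          for (int j = 0; j < p; ++j) w[j] += d * xi[j];
          w[p] += d;
        }
      }
    }
    if (pgmax - pgmin <= tol) {
      if (active == n) break;
      // converged on the shrunken problem: restore and verify on full set
      active = n;
      pgmax_old = inf;
      pgmin_old = -inf;
      continue;
    }
    pgmax_old = (pgmax <= 0.0) ? inf : pgmax;
    pgmin_old = (pgmin >= 0.0) ? -inf : pgmin;
  }

  NumericVector out(p + 1);
  for (int j = 0; j <= p; ++j) out[j] = w[j];
  return out;
}
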