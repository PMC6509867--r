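#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the per-stage penalized least-squares
// objective
//   f(b) = (1/m) ||y - X b||^2 + lambda * ( a * ||b||_1 + (1-a) * ||b||_2^2 )
// over a decreasing lambda grid with warm starts and an active-set
// strategy: iterate over the currently nonzero coefficients until
// convergence, then run one full sweep; finish when the full sweep changes
// no coefficient beyond tol. X is expected column-standardized but the
// update only assumes finite column norms.
//
// Coordinate update (r = y - X b is the full residual, maintained):
//   c_j = (2/m) * x_j' r + (2/m) * ||x_j||^2 * b_j
//   d_j = (2/m) * ||x_j||^2 + 2 * lambda * (1 - a)
//   b_j <- soft(c_j, lambda * a) / d_j

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".enet_path_cd")]]
List enet_path_cd(NumericMatrix X, NumericVector y, NumericVector lambdas,
                  double alpha, double tol, int max_iter) {
  const int m = X.nrow(), n = X.ncol(), L = lambdas.size();
  NumericMatrix beta(L, n);
  IntegerVector iters(L);
  LogicalVector converged(L);
  NumericVector final_delta(L);

  std::vector<double> b(n, 0.0), r(y.begin(), y.end()), xn2(n, 0.0);
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    const double *xj = &X(0, j);
    for (int i = 0; i < m; ++i) s += xj[i] * xj[i];
    xn2[j] = s;
  }
  const double inv_m2 = 2.0 / m;
  std::vector<int> active;
  active.reserve(n);

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double l1 = lam * alpha;
    const double ridge = 2.0 * lam * (1.0 - alpha);
    int sweeps = 0;
    double max_delta = 0.0;
    bool ok = false;

    // one coordinate update; returns |change|
    auto update = [&](int j) -> double {
      const double bj = b[j];
      const double *xj = &X(0, j);
      double xr = 0.0;
      for (int i = 0; i < m; ++i) xr += xj[i] * r[i];
      const double cj = inv_m2 * xr + inv_m2 * xn2[j] * bj;
      const double dj = inv_m2 * xn2[j] + ridge;
      const double bn = (dj > 0.0) ? soft(cj, l1) / dj : 0.0;
      if (bn != bj) {
        const double diff = bj - bn;
        for (int i = 0; i < m; ++i) r[i] += xj[i] * diff;
        b[j] = bn;
        return std::abs(diff);
      }
      return 0.0;
    };

    while (sweeps < max_iter) {
      // full sweep over all coordinates
      max_delta = 0.0;
      ++sweeps;
      for (int j = 0; j < n; ++j) {
        const double d = update(j);
        if (d > max_delta) max_delta = d;
      }
      if (max_delta < tol) { ok = true; break; }
      // inner loop on the active (nonzero) set
      active.clear();
      for (int j = 0; j < n; ++j) if (b[j] != 0.0) active.push_back(j);
      while (sweeps < max_iter) {
        double inner_delta = 0.0;
        ++sweeps;
        for (int j : active) {
          const double d = update(j);
          if (d > inner_delta) inner_delta = d;
        }
        if (inner_delta < tol) break;
      }
    }
    iters[l] = sweeps;
    converged[l] = ok;
    final_delta[l] = max_delta;
    for (int j = 0; j < n; ++j) beta(l, j) = b[j];
  }
  return List::create(_["beta"] = beta, _["iters"] = iters,
                      _["converged"] = converged,
                      _["final_delta"] = final_delta);
}
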