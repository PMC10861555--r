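#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for
//   min_beta ||y - X beta||_2^2 + lambda * ( l2w * ||beta||_2^2 + sum_j w_j |beta_j| )
// over a decreasing lambda path with warm starts. X and y are used as given;
// centering/standardization and the intercept are handled by the R wrapper.
// w_j may be R_PosInf, which pins beta_j at zero.

static inline double soft_threshold(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".enet_cd_path")]]
NumericMatrix enet_cd_path(const NumericMatrix& X, const NumericVector& y,
                           const NumericVector& lambdas, double l2w,
                           const NumericVector& w, double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  if (w.size() != p) stop("length(w) must equal ncol(X)");

  NumericMatrix out(p, nl);
  std::vector<double> beta(p, 0.0), r(y.begin(), y.end()), cj(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    cj[j] = s;
  }

  std::vector<int> active;
  active.reserve(p);

  // One coordinate update; returns |change|.
  auto update = [&](int j, double lam) -> double {
    if (!R_finite(w[j]) || cj[j] <= 0.0) { // pinned or constant column
      if (beta[j] != 0.0) {
        for (int i = 0; i < n; ++i) r[i] += X(i, j) * beta[j];
        beta[j] = 0.0;
      }
      return 0.0;
    }
    double rho = cj[j] * beta[j];
    for (int i = 0; i < n; ++i) rho += X(i, j) * r[i];
    const double bnew = soft_threshold(rho, lam * w[j] / 2.0) /
                        (cj[j] + lam * l2w);
    const double d = bnew - beta[j];
    if (d != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= X(i, j) * d;
      beta[j] = bnew;
    }
    return std::abs(d);
  };

  for (int l = 0; l < nl; ++l) {
    const double lam = lambdas[l];
    int it = 0;
    while (it < maxit) {
      // full sweep; rebuild the active set
      double max_delta = 0.0;
      active.clear();
      for (int j = 0; j < p; ++j) {
        const double d = update(j, lam);
        if (d > max_delta) max_delta = d;
        if (beta[j] != 0.0) active.push_back(j);
      }
      ++it;
      if (max_delta < tol) break;
      // iterate over the active set only until it stabilizes
      while (it < maxit) {
        double md = 0.0;
        for (int j : active) {
          const double d = update(j, lam);
          if (d > md) md = d;
        }
        ++it;
        if (md < tol) break;
      }
    }
    for (int j = 0; j < p; ++j) out(j, l) = beta[j];
  }
  return out;
}
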