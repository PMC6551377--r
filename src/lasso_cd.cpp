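#include <Rcpp.h>
using namespace Rcpp;

// Soft-thresholding operator S(z, g) = sign(z) * max(|z| - g, 0).
inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Cyclic coordinate descent for the lasso objective
//   (1/(2N)) * sum_i (y_i - b0 - x_i'b)^2 + lambda * sum_j |b_j|
// over a decreasing grid of lambda values with warm starts.
//
// The intercept is unpenalized and handled by centering: on centered data the
// optimal intercept is ybar - xbar'b at every step. Columns need not be
// standardized; the update divides by the column's mean squared norm.
//
// Returns, per lambda: coefficients, intercept, iteration count, convergence
// flag, and the objective value recorded after every full sweep (used to
// assert monotone descent).
// [[Rcpp::export]]
List lasso_cd_path(const NumericMatrix& X, const NumericVector& y,
                   const NumericVector& lambda_grid,
                   double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), nl = lambda_grid.size();

  // center a working copy of X and y
  std::vector<double> xm(p), xx(p);
  NumericMatrix Xc(n, p);
  double ym = 0.0;
  for (int i = 0; i < n; ++i) ym += y[i];
  ym /= n;
  NumericVector yc(n);
  for (int i = 0; i < n; ++i) yc[i] = y[i] - ym;
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += X(i, j);
    m /= n;
    xm[j] = m;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      Xc(i, j) = X(i, j) - m;
      ss += Xc(i, j) * Xc(i, j);
    }
    xx[j] = ss / n; // mean squared norm of centered column
  }

  NumericVector beta(p);          // warm-started across the grid
  NumericVector r = clone(yc);    // residual y_c - Xc * beta
  NumericMatrix beta_out(p, nl);
  NumericVector b0_out(nl);
  IntegerVector iters(nl);
  LogicalVector converged(nl);
  List objectives(nl);

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda_grid[l];
    std::vector<double> obj_trace;
    bool conv = false;
    int it = 0;
    for (; it < max_iter; ++it) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        if (xx[j] <= 0.0) { beta[j] = 0.0; continue; }
        const double bj = beta[j];
        double rho = 0.0;
        for (int i = 0; i < n; ++i) rho += Xc(i, j) * r[i];
        rho = rho / n + xx[j] * bj;
        const double bnew = soft(rho, lam) / xx[j];
        const double d = bnew - bj;
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= Xc(i, j) * d;
          beta[j] = bnew;
          if (std::abs(d) > max_delta) max_delta = std::abs(d);
        }
      }
      // objective after the sweep
      double sse = 0.0, l1 = 0.0;
      for (int i = 0; i < n; ++i) sse += r[i] * r[i];
      for (int j = 0; j < p; ++j) l1 += std::abs(beta[j]);
      obj_trace.push_back(sse / (2.0 * n) + lam * l1);
      if (max_delta < tol) { conv = true; ++it; break; }
    }
    double b0 = ym;
    for (int j = 0; j < p; ++j) b0 -= beta[j] * xm[j];
    for (int j = 0; j < p; ++j) beta_out(j, l) = beta[j];
    b0_out[l] = b0;
    iters[l] = it;
    converged[l] = conv;
    objectives[l] = wrap(obj_trace);
  }

  return List::create(_["beta"] = beta_out, _["intercept"] = b0_out,
                      _["iterations"] = iters, _["converged"] = converged,
                      _["objective_trace"] = objectives);
}
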