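#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the lasso along a decreasing penalty grid.
//
// Solves, for each lambda in `lambda`,
//   min_b (1/2n) || y - X b ||^2 + lambda * || b ||_1
// with warm starts along the grid, zero initialization at the first lambda,
// and a fixed cyclic coordinate order, so the result is deterministic.
//
// X and y are used as given (no centering/scaling here; the R wrapper owns
// that). `norms2` must be colSums(X^2) / n, precomputed by the caller.
// Convergence: max absolute coefficient update in a full sweep < tol.
// [[Rcpp::export]]
List cd_lasso_path(const NumericMatrix& X, const NumericVector& y,
                   const NumericVector& lambda, const NumericVector& norms2,
                   double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), L = lambda.size();
  NumericMatrix beta(p, L);
  std::vector<double> b(p, 0.0);
  std::vector<double> r(y.begin(), y.end());
  IntegerVector iters(L);
  LogicalVector converged(L);

  for (int l = 0; l < L; ++l) {
    const double lam = lambda[l];
    int it = 0;
    bool ok = false;
    while (it < max_iter) {
      ++it;
      double maxdelta = 0.0;
      for (int j = 0; j < p; ++j) {
        const double vj = norms2[j];
        if (vj <= 0.0) continue;  // constant column: coefficient stays 0
        const double* xj = &X(0, j);
        double xr = 0.0;
        for (int i = 0; i < n; ++i) xr += xj[i] * r[i];
        // z is the unpenalized univariate solution times vj
        const double z = xr / n + vj * b[j];
        double bnew;
        if (z > lam)       bnew = (z - lam) / vj;
        else if (z < -lam) bnew = (z + lam) / vj;
        else               bnew = 0.0;
        const double d = bnew - b[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
          b[j] = bnew;
          const double ad = d < 0 ? -d : d;
          if (ad > maxdelta) maxdelta = ad;
        }
      }
      if (maxdelta < tol) { ok = true; break; }
    }
    iters[l] = it;
    converged[l] = ok;
    for (int j = 0; j < p; ++j) beta(j, l) = b[j];
  }

  return List::create(_["beta"] = beta, _["iters"] = iters,
                      _["converged"] = converged);
}
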