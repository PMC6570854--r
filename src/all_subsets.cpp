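#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exhaustive OLS over all 2^p predictor subsets, driven entirely by the
// precomputed Gram matrices so each candidate model costs one small
// Cholesky solve instead of a pass over the data.
//
//   G   = crossprod(cbind(1, X))   ((p+1) x (p+1), intercept first)
//   v   = crossprod(cbind(1, X), y)
//   yty = sum(y^2)
//
// For subset mask m (bit j set => predictor j included) the model always
// contains the intercept. Returns, for every mask 0..2^p-1:
//   rss  : residual sum of squares (NA if the subgram is not PD)
//   coef : coefficients in full (p+1) layout, zero where absent
//   dinv : diag of (G_sub)^-1 in full layout (for classical OLS SEs:
//          se_j = sqrt(sigma2 * dinv_j), sigma2 = rss / (n - k_coef))
// [[Rcpp::export]]
List all_subsets_ols(const arma::mat& G, const arma::vec& v, double yty) {
  const int p = static_cast<int>(G.n_rows) - 1;
  if (p < 0 || p > 25) stop("predictor count out of supported range");
  const std::size_t m = static_cast<std::size_t>(1) << p;

  arma::vec rss(m);
  arma::mat coefs(m, p + 1, arma::fill::zeros);
  arma::mat dinv(m, p + 1, arma::fill::zeros);

  arma::uvec full(p + 1);
  for (std::size_t mask = 0; mask < m; ++mask) {
    int nsub = 1;
    full[0] = 0;
    for (int j = 0; j < p; ++j)
      if ((mask >> j) & 1) full[nsub++] = static_cast<arma::uword>(j + 1);
    arma::uvec u = full.head(nsub);

    arma::mat Gs = G.submat(u, u);
    arma::vec vs = v.elem(u);
    arma::mat R;
    if (!arma::chol(R, Gs)) {
      rss[mask] = NA_REAL;
      continue;
    }
    arma::vec b = arma::solve(arma::trimatu(R),
                              arma::solve(arma::trimatl(R.t()), vs));
    double r = yty - arma::dot(b, vs);
    rss[mask] = (r > 0.0) ? r : 0.0;

    // diag of inv(Gs) with Gs = R'R: inv(Gs) = R^-1 R^-T, so the diagonal
    // is the rowwise sum of squares of R^-1.
    arma::mat Ri = arma::inv(arma::trimatu(R));
    arma::vec d = arma::sum(arma::square(Ri), 1);
    for (int t = 0; t < nsub; ++t) {
      coefs(mask, u[t]) = b[t];
      dinv(mask, u[t]) = d[t];
    }
    if ((mask & 0x3FFF) == 0) checkUserInterrupt();
  }

  return List::create(_["rss"] = rss, _["coef"] = coefs, _["dinv"] = dinv);
}
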