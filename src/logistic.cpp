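// Maximum-likelihood logistic regression by iteratively reweighted least
// squares.  The power-matching projection refits the same small model tens
// of thousands of times on subsamples, which is why this lives in C++; the
// fit is checked against stats::glm in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".logistic_irls_cpp")]]
List logistic_irls_cpp(const arma::mat& X, const arma::vec& y,
                       int max_iter = 30, double tol = 1e-9) {
  int p = X.n_cols;
  arma::vec beta(p, arma::fill::zeros);
  arma::mat XtWX(p, p);
  bool converged = false, ok = true;

  for (int it = 0; it < max_iter; ++it) {
    arma::vec eta = X * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w = arma::clamp(w, 1e-10, 0.25);
    arma::vec zres = eta + (y - mu) / w;
    XtWX = X.t() * (X.each_col() % w);
    arma::vec XtWz = X.t() * (w % zres);
    arma::vec beta_new;
    bool solved = arma::solve(beta_new, XtWX, XtWz,
                              arma::solve_opts::no_approx);
    if (!solved || !beta_new.is_finite()) { ok = false; break; }
    double delta = arma::abs(beta_new - beta).max();
    beta = beta_new;
    if (delta < tol) { converged = true; break; }
  }
  // quasi-separation: coefficients drifting without bound
  bool separated = arma::abs(beta).max() > 15.0;

  arma::vec se(p, arma::fill::value(NA_REAL));
  if (ok) {
    arma::mat cov;
    if (arma::inv_sympd(cov, XtWX)) {
      se = arma::sqrt(cov.diag());
    } else {
      ok = false;
    }
  }
  return List::create(_["beta"] = beta, _["se"] = se,
                      _["converged"] = converged && ok,
                      _["separated"] = separated);
}
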