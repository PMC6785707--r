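// Per-SNP logistic regression scan (additive dosage + covariates), IRLS.
// One fit per SNP column; rows with a missing dosage are dropped for that
// SNP only. Covariates and phenotype must be complete.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static bool irls_fit(const vec& y, const mat& X, vec& beta, double& se_last,
                     int maxit = 30, double tol = 1e-8) {
  const uword p = X.n_cols;
  for (int it = 0; it < maxit; ++it) {
    vec eta = X * beta;
    vec mu = 1.0 / (1.0 + exp(-eta));
    mu = clamp(mu, 1e-10, 1.0 - 1e-10);
    vec w = mu % (1.0 - mu);
    vec z = eta + (y - mu) / w;
    mat Xw = X.each_col() % w;
    mat XtWX = X.t() * Xw;
    vec XtWz = Xw.t() * z;
    vec beta_new;
    bool ok = solve(beta_new, XtWX, XtWz, solve_opts::no_approx);
    if (!ok) return false;
    double delta = max(abs(beta_new - beta));
    beta = beta_new;
    if (delta < tol) {
      mat cov;
      if (!inv_sympd(cov, XtWX)) {
        if (!inv(cov, XtWX)) return false;
      }
      se_last = std::sqrt(cov(p - 1, p - 1));
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix logistic_gwas_cpp(const arma::vec& y, const arma::mat& C,
                                      const arma::mat& G,
                                      const arma::vec& start) {
  const uword n = y.n_elem, m = G.n_cols, q = C.n_cols;
  Rcpp::NumericMatrix out(m, 5);  // beta, se, converged, n_used, monomorphic
  colnames(out) = Rcpp::CharacterVector::create("beta", "se", "converged",
                                                "n_used", "monomorphic");
  for (uword j = 0; j < m; ++j) {
    vec g = G.col(j);
    uvec keep = find_finite(g);
    bool subset = keep.n_elem < n;
    vec yj = subset ? y(keep) : y;
    vec gj = subset ? vec(g(keep)) : g;
    mat Cj = subset ? mat(C.rows(keep)) : C;
    uword nj = yj.n_elem;
    out(j, 3) = (double)nj;
    if (nj < q + 2 || gj.max() == gj.min()) {
      out(j, 0) = 0.0; out(j, 1) = NA_REAL; out(j, 2) = 0.0; out(j, 4) = 1.0;
      continue;
    }
    mat X(nj, q + 1);
    X.cols(0, q - 1) = Cj;
    X.col(q) = gj;
    vec beta(q + 1, fill::zeros);
    beta.head(q) = start;
    double se = NA_REAL;
    bool ok = irls_fit(yj, X, beta, se);
    out(j, 0) = beta(q);
    out(j, 1) = se;
    out(j, 2) = ok ? 1.0 : 0.0;
    out(j, 4) = 0.0;
  }
  return out;
}
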