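// Leave-one-out LDA misclassification fraction.
// Mirrors the R-side policy exactly (fit_lda/loo_cv): pooled covariance
// = within-class scatter / (n - 2); ridge lambda * trace/k escalated by
// decades from 1e-8 to 1e-2 when rcond <= 1e-10; a fold that stays
// singular, empties a class below 2 rows, or has k > n - 2 counts as a
// misclassification; a score of exactly 0 classifies as the negative class.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static bool solve_reg(const mat& S, const vec& d, vec& w, double rcond_tol) {
  double rc = rcond(S);
  if (std::isfinite(rc) && rc > rcond_tol) {
    return solve(w, S, d, solve_opts::no_approx);
  }
  double tr = trace(S) / S.n_rows;
  if (tr <= 0) tr = 1.0;
  for (double lambda = 1e-8; lambda <= 1e-2 * 1.0000001; lambda *= 10) {
    mat M = S + lambda * tr * eye(S.n_rows, S.n_rows);
    rc = rcond(M);
    if (std::isfinite(rc) && rc > rcond_tol) {
      return solve(w, M, d, solve_opts::no_approx);
    }
  }
  return false;
}

// [[Rcpp::export]]
double loo_lda_cost_cpp(const arma::mat& X, const arma::ivec& y) {
  const uword n = X.n_rows, k = X.n_cols;
  const double rcond_tol = 1e-10;
  uword wrong = 0;
  for (uword i = 0; i < n; ++i) {
    // fold totals without row i
    uvec keep = regspace<uvec>(0, n - 1);
    keep.shed_row(i);
    mat Xf = X.rows(keep);
    ivec yf = y.elem(keep);
    uword nf = Xf.n_rows;
    uvec idx_p = find(yf == 1), idx_n = find(yf == 0);
    if (idx_p.n_elem < 2 || idx_n.n_elem < 2 || k > nf - 2) {
      ++wrong;
      continue;
    }
    mat Xp = Xf.rows(idx_p), Xn = Xf.rows(idx_n);
    rowvec mp = mean(Xp, 0), mn = mean(Xn, 0);
    mat Cp = Xp.each_row() - mp, Cn = Xn.each_row() - mn;
    mat S = (Cp.t() * Cp + Cn.t() * Cn) / double(nf - 2);
    vec w;
    if (!solve_reg(S, (mp - mn).t(), w, rcond_tol)) {
      ++wrong;
      continue;
    }
    double bias = -dot(w, 0.5 * (mp + mn).t());
    double s = dot(w, X.row(i).t()) + bias;
    int pred = (s > 0) ? 1 : 0;
    if (pred != y(i)) ++wrong;
  }
  return double(wrong) / double(n);
}
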