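// Log-domain Sinkhorn solver for entropic optimal transport between
// weighted point clouds with squared-Euclidean ground cost.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// pairwise squared Euclidean distances, n x m
static mat sqdist(const mat& X, const mat& Y) {
  vec xn = sum(square(X), 1);
  vec yn = sum(square(Y), 1);
  mat C = -2.0 * X * Y.t();
  C.each_col() += xn;
  C.each_row() += yn.t();
  C.elem(find(C < 0)).zeros();  // numerical floor
  return C;
}

// row-wise log-sum-exp of M
static vec lse_rows(const mat& M) {
  vec mx = max(M, 1);
  // guard against -inf rows (cannot occur with finite weights, but be safe)
  vec out(M.n_rows);
  for (uword i = 0; i < M.n_rows; ++i) {
    double m = mx(i);
    if (!std::isfinite(m)) { out(i) = m; continue; }
    out(i) = m + std::log(accu(exp(M.row(i) - m)));
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_sinkhorn(const arma::mat& X, const arma::mat& Y,
                        const arma::vec& a, const arma::vec& b,
                        double eps, double tol, int max_iter,
                        bool return_plan) {
  const uword n = X.n_rows, m = Y.n_rows;
  mat C = sqdist(X, Y);
  vec loga = log(a), logb = log(b);
  vec f(n, fill::zeros), g(m, fill::zeros);
  double err = datum::inf;
  // epsilon annealing: warm-start the potentials from a heavily blurred
  // problem and halve the temperature down to the target, which cuts the
  // iteration count at small eps by orders of magnitude
  double cmax = C.max();
  for (double eps_cur = cmax / 2.0; eps_cur > eps; eps_cur *= 0.7) {
    for (int r = 0; r < 2; ++r) {
      mat Mf = -C;
      Mf.each_row() += g.t();
      Mf /= eps_cur;
      Mf.each_row() += logb.t();
      f = -eps_cur * lse_rows(Mf);
      mat Mg = -C;
      Mg.each_col() += f;
      Mg /= eps_cur;
      Mg.each_col() += loga;
      g = -eps_cur * lse_rows(Mg.t());
    }
  }
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    // f_i = -eps * LSE_j[(g_j - C_ij)/eps + log b_j]
    mat Mf = -C;
    Mf.each_row() += g.t();
    Mf /= eps;
    Mf.each_row() += logb.t();
    f = -eps * lse_rows(Mf);
    mat Mg = -C;
    Mg.each_col() += f;
    Mg /= eps;
    Mg.each_col() += loga;
    g = -eps * lse_rows(Mg.t());
    // after the g-update, column marginals are exact; check row marginals
    // (every 5 iterations: the check costs as much as an update)
    if (it % 5 == 4 || it == max_iter - 1) {
      mat logP = -C;
      logP.each_col() += f;
      logP.each_row() += g.t();
      logP /= eps;
      logP.each_col() += loga;
      logP.each_row() += logb.t();
      vec row = exp(lse_rows(logP));
      err = accu(abs(row - a));
      if (err <= tol) { ++it; break; }
    }
  }
  mat logP = -C;
  logP.each_col() += f;
  logP.each_row() += g.t();
  logP /= eps;
  logP.each_col() += loga;
  logP.each_row() += logb.t();
  mat P = exp(logP);
  // transport cost + eps * sum P (log P - 1), with 0 log 0 = 0
  double cost = accu(P % C);
  double ent = 0.0;
  for (uword i = 0; i < n; ++i)
    for (uword j = 0; j < m; ++j) {
      double p = P(i, j);
      if (p > 0) ent += p * (logP(i, j) - 1.0);
    }
  cost += eps * ent;
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("cost") = cost,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = (err <= tol),
    Rcpp::Named("marginal_error") = err);
  if (return_plan) out["plan"] = P;
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_sqdist(const arma::mat& X, const arma::mat& Y) {
  return sqdist(X, Y);
}
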