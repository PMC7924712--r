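// ADMM inner loop for the affine-constrained l1,2 self-representation
// problem. Mirrors the pure-R reference loop in solve_smba() exactly:
// beta-update through the constrained ridge solve (Woodbury when m < n),
// row-wise block soft-threshold, dual ascent, relative primal residual.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".admm_l12_cpp")]]
Rcpp::List admm_l12(const arma::mat& V, double lam, double rho,
                    double delta, int max_iter) {
  const uword m = V.n_rows, n = V.n_cols;
  const mat G = V.t() * V;
  const bool lowrank = m < n;
  mat R;                      // Cholesky factor of the solve matrix
  if (lowrank) {
    R = chol(rho * eye<mat>(m, m) + V * V.t());
  } else {
    R = chol(G + rho * eye<mat>(n, n));
  }
  auto ainv = [&](const mat& Y) -> mat {
    if (lowrank) {
      mat t = solve(trimatu(R), solve(trimatl(R.t()), V * Y));
      return (Y - V.t() * t) / rho;
    }
    return solve(trimatu(R), solve(trimatl(R.t()), Y));
  };

  const vec a = ainv(ones<mat>(n, 1));   // (G + rho I)^{-1} 1
  const double s = accu(a);
  const double kappa = lam / rho;

  mat theta(n, n, fill::zeros), mu(n, n, fill::zeros), beta;
  double eps = datum::inf;
  int t = 0;
  std::vector<double> resid;
  resid.reserve(256);

  while (eps > delta && t < max_iter) {
    mat U = ainv(G + rho * theta - mu);
    rowvec corr = (sum(U, 0) - 1.0) / s;
    beta = U - a * corr;                       // columns sum to 1
    mat M = beta + mu / rho;
    vec rn = sqrt(sum(square(M), 1));
    for (uword i = 0; i < n; ++i) {
      const double sc = rn[i] > 0 ? std::max(0.0, 1.0 - kappa / rn[i]) : 0.0;
      M.row(i) *= sc;
    }
    theta = M;
    mu += rho * (beta - theta);
    eps = norm(beta - theta, "fro") / std::max(1.0, norm(beta, "fro"));
    ++t;
    resid.push_back(eps);
  }

  return Rcpp::List::create(
      Rcpp::Named("theta") = theta,
      Rcpp::Named("iterations") = t,
      Rcpp::Named("eps") = eps,
      Rcpp::Named("residuals") = resid);
}
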