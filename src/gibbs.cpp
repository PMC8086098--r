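#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Semi-conjugate Gibbs sampler for linear regression.
//
// Model: y = X beta + e, e ~ N(0, 1/tau), with independent normal priors
// beta_j ~ N(m0_j, v0_j) and tau ~ Gamma(a0, b0) (shape/rate).
//
// Full conditionals:
//   beta | tau : N(A^{-1} b, A^{-1}),  A = tau X'X + V0^{-1},
//                b = tau X'y + V0^{-1} m0
//   tau | beta : Gamma(a0 + n/2, b0 + ||y - X beta||^2 / 2)
//
// The coefficient update is done in a whitened basis: with W = diag(sqrt(v0))
// and B = W X'X W = Q L Q' (eigendecomposition, computed once),
//   A^{-1} = W Q diag(1/(tau*l_i + 1)) Q' W,
// so each iteration costs two Q matrix-vector products and no factorisation.
// The residual sum of squares uses the precomputed Gram matrix:
//   rss = y'y - 2 beta'X'y + beta'(X'X)beta.
//
// Uses R's RNG so draws are reproducible via set.seed() on the R side.
// [[Rcpp::export]]
List gibbs_chain_cpp(const arma::mat& X, const arma::vec& y,
                     const arma::vec& m0, const arma::vec& v0,
                     double a0, double b0,
                     int n_iter, int burn_in) {
  const int n = X.n_rows, q = X.n_cols;
  const arma::mat XtX = X.t() * X;
  const arma::vec Xty = X.t() * y;
  const double yty = arma::dot(y, y);
  const arma::vec w = arma::sqrt(v0);
  const arma::vec V0m0 = m0 / v0;

  const arma::mat B = (XtX.each_col() % w).eval().each_row() % w.t();
  arma::vec lambda;
  arma::mat Q;
  if (!arma::eig_sym(lambda, Q, arma::symmatu(B)))
    stop("eigendecomposition of the whitened Gram matrix failed");

  const int keep = n_iter - burn_in;
  arma::mat beta_draws(keep, q);
  arma::vec tau_draws(keep);

  double tau = a0 / b0;              // start at prior mean
  arma::vec beta(q), b(q), u(q), z(q), d(q);

  for (int it = 0; it < n_iter; ++it) {
    b = tau * Xty + V0m0;
    d = 1.0 / (tau * lambda + 1.0);
    // mean in whitened basis, then one sqrt(d)-scaled standard-normal kick
    u = Q.t() * (w % b);
    for (int j = 0; j < q; ++j)
      u(j) = d(j) * u(j) + std::sqrt(d(j)) * R::norm_rand();
    beta = w % (Q * u);

    double rss = yty - 2.0 * arma::dot(beta, Xty) +
      arma::dot(beta, XtX * beta);
    if (rss < 0.0) rss = 0.0;        // guard against round-off
    // R::rgamma is parameterised by shape and SCALE
    tau = R::rgamma(a0 + 0.5 * n, 1.0 / (b0 + 0.5 * rss));

    if (it >= burn_in) {
      beta_draws.row(it - burn_in) = beta.t();
      tau_draws(it - burn_in) = tau;
    }
  }

  return List::create(_["beta"] = beta_draws, _["tau"] = tau_draws);
}
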