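#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// First-order vector autoregression x(t+1) = A x(t) + eps, eps ~ N(0, sd^2 I).
// Returns an n_channels x n_steps matrix. Uses R's RNG.
// [[Rcpp::export]]
arma::mat var1_sim_cpp(const arma::mat& A, const arma::vec& x0,
                       double noise_sd, int n_steps) {
  const int n = A.n_rows;
  arma::mat out(n, n_steps);
  arma::vec x = x0, eps(n);
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) eps[i] = noise_sd * norm_rand();
    x = A * x + eps;
    out.col(t) = x;
  }
  return out;
}
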