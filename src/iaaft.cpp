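#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One IAAFT surrogate of x: alternate (i) imposing the Fourier amplitude
// spectrum of x while keeping the current phases and (ii) rank-ordering the
// original sample values onto the result. Stops when the rank ordering is
// unchanged between iterations or after max_iter iterations. The initial
// shuffle uses R's RNG (reproducible under set.seed()).
// [[Rcpp::export]]
arma::vec iaaft_cpp(const arma::vec& x, int max_iter) {
  const int n = x.n_elem;
  arma::vec amp = arma::sort(x);
  arma::vec target_amp = arma::abs(arma::fft(x));

  // Fisher-Yates shuffle for the starting point
  arma::vec y = x;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(y[i], y[j]);
  }

  arma::uvec prev(n, arma::fill::zeros);
  bool have_prev = false;
  for (int it = 0; it < max_iter; ++it) {
    arma::cx_vec fy = arma::fft(y);
    for (int k2 = 0; k2 < n; ++k2) {
      double m = std::abs(fy[k2]);
      fy[k2] = (m > 0.0) ? fy[k2] * (target_amp[k2] / m)
                         : std::complex<double>(target_amp[k2], 0.0);
    }
    arma::vec z = arma::real(arma::ifft(fy));
    arma::uvec ord = arma::sort_index(z);
    for (int k2 = 0; k2 < n; ++k2) y[ord[k2]] = amp[k2];
    if (have_prev && arma::all(ord == prev)) break;
    prev = ord;
    have_prev = true;
  }
  return y;
}
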