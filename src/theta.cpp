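#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Euler-Maruyama integration of the coupled stochastic theta-neuron network
//   dtheta_j = [(1 - cos th_j) + (1 + cos th_j) I_j] dt
//                + (1 + cos th_j) * noise_sd * sqrt(dt) dW_j
//   I_j = I0_j + (K/N) sum_{i != j} a_ij [1 - cos(th_i - th_i^s)]
// Phases start at the stable fixed point and are wrapped to (-pi, pi];
// a spike is recorded at each upward crossing of theta = pi.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List theta_sim_cpp(const arma::mat& a, const arma::vec& i0,
                   double noise_sd, double k, double dt, int n_steps) {
  const int n = a.n_rows;
  // stable fixed point for subthreshold nodes; supra-threshold nodes
  // (i0 >= 0) have none and use the SNIC remnant at 0 as reference phase
  arma::vec theta_s(n);
  for (int j = 0; j < n; ++j)
    theta_s[j] = (i0[j] < 0.0)
      ? -std::acos((1.0 + i0[j]) / (1.0 - i0[j])) : 0.0;
  arma::vec theta = theta_s;
  const double sq = noise_sd * std::sqrt(dt);
  // input to node j sums a_ij over source nodes i
  arma::mat at = a.t();
  std::vector< std::vector<double> > spikes(n);
  arma::vec f(n), drive(n);
  for (int t = 0; t < n_steps; ++t) {
    f = 1.0 - arma::cos(theta - theta_s);
    drive = (k / n) * (at * f);
    for (int j = 0; j < n; ++j) {
      double c = std::cos(theta[j]);
      double th = theta[j]
        + dt * ((1.0 - c) + (1.0 + c) * (i0[j] + drive[j]))
        + (1.0 + c) * sq * norm_rand();
      if (th > M_PI) {
        th -= 2.0 * M_PI;
        spikes[j].push_back((t + 1) * dt);
      } else if (th < -M_PI) {
        th += 2.0 * M_PI;
      }
      theta[j] = th;
    }
  }
  List out(n);
  for (int j = 0; j < n; ++j)
    out[j] = NumericVector(spikes[j].begin(), spikes[j].end());
  return out;
}
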