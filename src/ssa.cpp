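// Exact stochastic simulation (direct method) of the coarse-grained
// sRNA silencing system. Seven elementary reactions over species (m, s, p):
//   1. mRNA birth        alpha_m        (+1, 0, 0)
//   2. mRNA decay        beta_m * m     (-1, 0, 0)
//   3. sRNA birth        alpha_s        ( 0,+1, 0)
//   4. sRNA decay        beta_s * s     ( 0,-1, 0)
//   5. codegradation     k * s * m      (-1,-1, 0)
//   6. protein birth     gamma * m      ( 0, 0,+1)
//   7. protein decay     beta_p * p     ( 0, 0,-1)
// A self-contained mt19937_64 stream per trajectory keeps runs bitwise
// reproducible and independent of R's RNG state.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List ssa_run(NumericVector rates, IntegerVector init, double t_burn_in,
             double t_sample, double sample_interval, int n_traj,
             double seed) {
  const double alpha_m = rates["alpha_m"], beta_m = rates["beta_m"],
               alpha_s = rates["alpha_s"], beta_s = rates["beta_s"],
               k = rates["k"], gamma = rates["gamma"], beta_p = rates["beta_p"];
  const double t_end = t_burn_in + t_sample;
  const int n_samp = (int)std::floor(t_sample / sample_interval) + 1;

  NumericMatrix mean_traj(n_traj, 3), var_traj(n_traj, 3), cv2_traj(n_traj, 3);
  double total_events = 0.0;

  for (int traj = 0; traj < n_traj; ++traj) {
    std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL +
                        (uint64_t)(traj + 1));
    std::uniform_real_distribution<double> unif(
        std::numeric_limits<double>::min(), 1.0);
    double m = init[0], s = init[1], p = init[2];
    double t = 0.0, t_next = t_burn_in;
    int isamp = 0;
    // online moments over sampled states (Welford)
    double n_obs = 0.0, mu[3] = {0, 0, 0}, M2[3] = {0, 0, 0};
    while (isamp < n_samp) {
      double a1 = alpha_m, a2 = beta_m * m, a3 = alpha_s, a4 = beta_s * s,
             a5 = k * s * m, a6 = gamma * m, a7 = beta_p * p;
      double a0 = a1 + a2 + a3 + a4 + a5 + a6 + a7;
      double tau = (a0 > 0.0) ? -std::log(unif(rng)) / a0 : R_PosInf;
      // record all sample points passed before the next event fires
      while (isamp < n_samp && t + tau > t_next) {
        double state[3] = {m, s, p};
        n_obs += 1.0;
        for (int j = 0; j < 3; ++j) {
          double d = state[j] - mu[j];
          mu[j] += d / n_obs;
          M2[j] += d * (state[j] - mu[j]);
        }
        ++isamp;
        t_next += sample_interval;
      }
      if (isamp >= n_samp || t + tau > t_end) break;
      t += tau;
      total_events += 1.0;
      double r = unif(rng) * a0;
      if (r < a1) { m += 1; }
      else if (r < a1 + a2) { m -= 1; }
      else if (r < a1 + a2 + a3) { s += 1; }
      else if (r < a1 + a2 + a3 + a4) { s -= 1; }
      else if (r < a1 + a2 + a3 + a4 + a5) { m -= 1; s -= 1; }
      else if (r < a1 + a2 + a3 + a4 + a5 + a6) { p += 1; }
      else { p -= 1; }
    }
    for (int j = 0; j < 3; ++j) {
      mean_traj(traj, j) = mu[j];
      var_traj(traj, j) = (n_obs > 1.0) ? M2[j] / (n_obs - 1.0) : NA_REAL;
      cv2_traj(traj, j) = (mu[j] > 0.0 && n_obs > 1.0)
          ? (M2[j] / (n_obs - 1.0)) / (mu[j] * mu[j]) : NA_REAL;
    }
  }
  return List::create(_["mean_traj"] = mean_traj, _["var_traj"] = var_traj,
                      _["cv2_traj"] = cv2_traj, _["n_samples"] = n_samp,
                      _["event_count"] = total_events);
}
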