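#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Ensemble kernel for the biased fragmentation process.
//
// Each simulation starts from one region of volume root_volume and repeats:
// pick a leaf with probability proportional to volume^mu, split it into two
// halves, perturb the halves by a multiplicative factor r ~ Normal(1,
// noise_sd) (child volumes v*r/2 and v*(2-r)/2, so the sum is preserved),
// until n_pu leaves exist. Returns the within-run standard deviation of
// ln(leaf volume) for each of n_sims independent runs.
//
// Works in log-volume space throughout; selection weights are computed with
// max-subtraction so large |mu * ln v| cannot overflow. Uses R's RNG
// (unif_rand / norm_rand) so set.seed() makes runs reproducible; per step,
// one uniform draw selects the leaf and normal draws produce the noise
// factor (re-drawn while r <= 0.02 or r >= 1.98 to keep volumes positive).

// [[Rcpp::export]]
NumericVector cpp_sigma_ensemble(int n_pu, double mu, double noise_sd,
                                 int n_sims, double root_volume) {
  if (n_pu < 1) stop("n_pu must be >= 1");
  if (n_sims < 1) stop("n_sims must be >= 1");
  if (noise_sd < 0 || noise_sd >= 0.5) stop("noise_sd must be in [0, 0.5)");
  if (root_volume <= 0) stop("root_volume must be positive");

  NumericVector out(n_sims);
  std::vector<double> lv(n_pu);
  std::vector<double> w(n_pu);

  for (int s = 0; s < n_sims; ++s) {
    lv[0] = std::log(root_volume);
    for (int k = 1; k < n_pu; ++k) {
      int idx;
      if (mu == 0.0) {
        idx = (int)(unif_rand() * k);
        if (idx >= k) idx = k - 1;
      } else {
        double mx = mu * lv[0];
        for (int i = 1; i < k; ++i) {
          double z = mu * lv[i];
          if (z > mx) mx = z;
        }
        double tot = 0.0;
        for (int i = 0; i < k; ++i) {
          w[i] = std::exp(mu * lv[i] - mx);
          tot += w[i];
        }
        double u = unif_rand() * tot, c = 0.0;
        idx = k - 1;
        for (int i = 0; i < k; ++i) {
          c += w[i];
          if (u <= c) { idx = i; break; }
        }
      }
      double r = 1.0;
      if (noise_sd > 0.0) {
        do {
          r = 1.0 + noise_sd * norm_rand();
        } while (r <= 0.02 || r >= 1.98);
      }
      double old = lv[idx];
      lv[idx] = old + std::log(r / 2.0);
      lv[k] = old + std::log((2.0 - r) / 2.0);
    }
    if (n_pu > 1) {
      double m = 0.0;
      for (int i = 0; i < n_pu; ++i) m += lv[i];
      m /= n_pu;
      double v = 0.0;
      for (int i = 0; i < n_pu; ++i) {
        double d = lv[i] - m;
        v += d * d;
      }
      out[s] = std::sqrt(v / (n_pu - 1));
    } else {
      out[s] = 0.0;
    }
  }
  return out;
}
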