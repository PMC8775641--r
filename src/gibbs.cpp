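#include <Rcpp.h>
using namespace Rcpp;

// Sequential-scan Gibbs sampler for a {0,1} Ising model.
// Full conditional: P(x_j = 1 | rest) = plogis(tau_j + sum_k omega_jk x_k).
// Uses R's RNG so set.seed() in R controls reproducibility.
// [[Rcpp::export(name = ".gibbs_sample")]]
IntegerMatrix gibbs_sample(NumericVector thresholds, NumericMatrix couplings,
                           int n, int burn_in, int thin) {
  const int p = thresholds.size();
  IntegerMatrix out(n, p);
  std::vector<int> x(p);
  for (int j = 0; j < p; ++j) x[j] = (unif_rand() < 0.5) ? 1 : 0;

  auto sweep = [&]() {
    for (int j = 0; j < p; ++j) {
      double eta = thresholds[j];
      for (int k = 0; k < p; ++k)
        if (x[k]) eta += couplings(j, k);
      // couplings has zero diagonal, so x[j] never contributes
      double pr = 1.0 / (1.0 + std::exp(-eta));
      x[j] = (unif_rand() < pr) ? 1 : 0;
    }
  };

  for (int s = 0; s < burn_in; ++s) sweep();
  for (int i = 0; i < n; ++i) {
    for (int s = 0; s < thin; ++s) sweep();
    for (int j = 0; j < p; ++j) out(i, j) = x[j];
  }
  return out;
}
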