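#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step explicit Euler for mass-action networks.
// Reactions are encoded as reactant indices r1 (1-based, required) and r2
// (0 = unimolecular), product indices p1/p2 (0 = none), and forward rate
// constants k. Returns concentrations at the requested sample times.
// [[Rcpp::export]]
NumericMatrix euler_mass_action(NumericVector x0,
                                IntegerVector r1, IntegerVector r2,
                                IntegerVector p1, IntegerVector p2,
                                NumericVector k,
                                double dt, NumericVector sample_times) {
  const int n_sp = x0.size();
  const int n_rx = k.size();
  const int n_t = sample_times.size();
  std::vector<double> x(x0.begin(), x0.end());
  NumericMatrix out(n_t, n_sp);

  double t = 0.0;
  int s = 0;
  // record any leading sample times at t = 0
  while (s < n_t && sample_times[s] <= 0.0) {
    for (int i = 0; i < n_sp; ++i) out(s, i) = x[i];
    ++s;
  }
  while (s < n_t) {
    double target = sample_times[s];
    std::vector<double> v(n_rx);
    while (t < target) {
      double h = std::min(dt, target - t);
      // all fluxes evaluated at the step start (strict explicit Euler)
      for (int j = 0; j < n_rx; ++j) {
        v[j] = h * k[j] * x[r1[j] - 1];
        if (r2[j] > 0) v[j] *= x[r2[j] - 1];
      }
      for (int j = 0; j < n_rx; ++j) {
        x[r1[j] - 1] -= v[j];
        if (r2[j] > 0) x[r2[j] - 1] -= v[j];
        if (p1[j] > 0) x[p1[j] - 1] += v[j];
        if (p2[j] > 0) x[p2[j] - 1] += v[j];
      }
      t += h;
    }
    for (int i = 0; i < n_sp; ++i) out(s, i) = x[i];
    ++s;
    if (s % 8 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
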