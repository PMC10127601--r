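#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama integration (Ito) of the stochastic logistic SDE
//   dx = x/tau (1 - x/K) dt + sqrt(sigma/tau) x dW
// for many independent paths sharing one day grid. Between consecutive
// observation days the interval is split into equal substeps no longer than
// dt_cap (callers pass min(0.02*tau, 0.02) so the discretisation error is
// negligible relative to sampling noise). Multiplicative-noise Euler steps
// can cross zero; paths are floored at floor_val to prevent absorption.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix slm_paths_cpp(NumericVector days, NumericVector x0,
                            NumericVector K, NumericVector sigma,
                            NumericVector tau, double dt_cap,
                            double floor_val) {
  const int npath = x0.size();
  const int nd = days.size();
  NumericMatrix out(npath, nd);

  for (int p = 0; p < npath; ++p) {
    const double k = K[p % K.size()];
    const double sg = sigma[p % sigma.size()];
    const double tu = tau[p % tau.size()];
    const double noise = std::sqrt(sg / tu);
    const double dtmax = std::min(dt_cap, 0.02 * tu);
    double x = x0[p];
    out(p, 0) = x;
    for (int j = 1; j < nd; ++j) {
      const double gap = days[j] - days[j - 1];
      const int nstep = (int)std::ceil(gap / dtmax);
      const double dt = gap / nstep;
      const double sdt = std::sqrt(dt);
      for (int s = 0; s < nstep; ++s) {
        const double z = norm_rand();
        x += x / tu * (1.0 - x / k) * dt + noise * x * sdt * z;
        if (x < floor_val) x = floor_val;
      }
      out(p, j) = x;
    }
  }
  return out;
}
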