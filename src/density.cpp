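#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Evaluate the sum of Gaussian kernels centred on spike times at a uniform
// grid. Grid points are t0 + i*dt for i in 0..(n-1); kernels truncated at
// 5 sigma. Uses the recurrence g_{i+1} = g_i * a_i, a_{i+1} = a_i * q with
// q = exp(-dt^2/sigma^2), so each grid point costs two multiplies instead
// of an exp; the accumulated rounding over the ~10*sigma/dt points of one
// kernel stays near machine precision.
// [[Rcpp::export(name = ".gauss_density_cpp")]]
NumericVector gauss_density_cpp(NumericVector spikes, double t0, int n,
                                double dt, double sigma) {
  NumericVector out(n);
  const double norm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double half_width = 5.0 * sigma;
  const double q = std::exp(-dt * dt * 2.0 * inv2s2);
  for (R_xlen_t s = 0; s < spikes.size(); ++s) {
    const double ts = spikes[s];
    int lo = (int)std::ceil((ts - half_width - t0) / dt);
    int hi = (int)std::floor((ts + half_width - t0) / dt);
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    if (lo > hi) continue;
    const double d0 = t0 + lo * dt - ts;
    double g = norm * std::exp(-d0 * d0 * inv2s2);
    // a_i = exp(-(2*d_i*dt + dt^2) * inv2s2)
    double a = std::exp(-(2.0 * d0 * dt + dt * dt) * inv2s2);
    for (int i = lo; i <= hi; ++i) {
      out[i] += g;
      g *= a;
      a *= q;
    }
  }
  return out;
}
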