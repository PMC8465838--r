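#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact evaluation of the calcium forward model
//   c(t) = sum_spikes A * exp(-(t-ts)/tau2) * (1 - exp(-(t-ts)/tau1))
// on a regular sample grid t = h, 2h, ..., nbins*h. The kernel is the
// difference of two exponentials (rates 1/tau2 and 1/tau1 + 1/tau2), so the
// trace is propagated analytically between events; no numerical convolution.

// [[Rcpp::export]]
NumericMatrix calcium_traces_cpp(const IntegerVector spk_neuron,
                                 const NumericVector spk_time, int n_neurons,
                                 double duration, double h, double A,
                                 double tau1, double tau2) {
  const int nbins = (int)std::floor(duration / h + 1e-9);
  NumericMatrix out(n_neurons, nbins);
  const double rk = 1.0 / tau1 + 1.0 / tau2;  // fast (rise-limiting) rate

  // group spike indices by neuron (times assumed sorted within neuron)
  std::vector<std::vector<double>> spk(n_neurons);
  for (int s = 0; s < spk_neuron.size(); ++s)
    spk[spk_neuron[s] - 1].push_back(spk_time[s]);

  for (int i = 0; i < n_neurons; ++i) {
    double c2 = 0.0, ck = 0.0, t_cur = 0.0;
    size_t si = 0;
    const std::vector<double> &ts = spk[i];
    for (int b = 0; b < nbins; ++b) {
      const double t_samp = (b + 1) * h;
      while (si < ts.size() && ts[si] <= t_samp) {
        const double gap = ts[si] - t_cur;
        c2 *= std::exp(-gap / tau2);
        ck *= std::exp(-gap * rk);
        c2 += A;
        ck += A;
        t_cur = ts[si];
        ++si;
      }
      const double gap = t_samp - t_cur;
      c2 *= std::exp(-gap / tau2);
      ck *= std::exp(-gap * rk);
      t_cur = t_samp;
      out(i, b) = c2 - ck;
    }
  }
  return out;
}
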