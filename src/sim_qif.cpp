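#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Quadratic integrate-and-fire network with spike-frequency adaptation,
// depressing alpha-function synapses and independent Poisson drive.
//
// State per neuron: v (mV), w (adaptation current, mV), and two linear
// filter pairs (aE, sE) and (aI, sI) realizing alpha-function synaptic
// inputs:  a' = -a/tau,  s' = (e*a - s)/tau,  so that an impulse a += A
// yields s(t) = A * (t/tau) * exp(1 - t/tau), peaking at A when t = tau.
// The deterministic part advances with classical RK4; the white-noise term
// g_xi * xi(t) inside the 1/tau_v bracket is added once per step as
// g_xi * sqrt(dt) * N(0,1) / tau_v (Euler-Maruyama splitting).
//
// adj is indexed [target, source]: adj(i, j) != 0 when j projects to i.
// Uses R's RNG so results are reproducible under set.seed().

struct Deriv {
  double dv, dw, daE, dsE, daI, dsI;
};

static inline void deriv(double v, double w, double aE, double sE,
                         double aI, double sI, double Kv, double vr,
                         double vt, double tauv, double Kw, double tauw,
                         double tauE, double tauI, double i_ext, Deriv &d) {
  const double e1 = M_E;
  d.dv = (Kv * (v - vr) * (v - vt) - w + (sE - sI) + i_ext) / tauv;
  d.dw = (Kw * (v - vr) - w) / tauw;
  d.daE = -aE / tauE;
  d.dsE = (e1 * aE - sE) / tauE;
  d.daI = -aI / tauI;
  d.dsI = (e1 * aI - sI) / tauI;
}

// [[Rcpp::export]]
List sim_qif_cpp(const IntegerMatrix adj, const IntegerVector inhibitory,
                 List neuron, List synapse, double duration, double dt,
                 double i_ext, IntegerVector record_v_ids,
                 int record_every) {
  const int n = adj.nrow();
  if (adj.ncol() != n) stop("adjacency must be square");
  if (inhibitory.size() != n) stop("labels length mismatch");

  const double vr = neuron["v_r"], vt = neuron["v_t"], vp = neuron["v_p"],
               vc = neuron["v_c"], tauv = neuron["tau_v"],
               Kv = neuron["K_v"], gxi = neuron["g_xi"],
               tauw = neuron["tau_w"], Kw = neuron["K_w"],
               dw_inc = neuron["delta_w"];
  const double gE = synapse["g_E"], gI = synapse["g_I"],
               tauE = synapse["tau_E"], tauI = synapse["tau_I"],
               delay = synapse["delay_syn"], alpha = synapse["alpha"],
               tauD = synapse["tau_D"], lambda = synapse["lambda_ext"];

  const long nsteps = (long)std::floor(duration / dt + 0.5);
  const int dsteps = (int)std::floor(delay / dt + 0.5);
  const double p_ext = lambda * dt / 1000.0;  // lambda in Hz, dt in ms
  const double noise_amp = gxi * std::sqrt(dt) / tauv;
  const double d_relax = std::exp(-dt / tauD);

  std::vector<double> v(n), w(n, 0.0), aE(n, 0.0), sE(n, 0.0), aI(n, 0.0),
      sI(n, 0.0), D(n, 1.0);

  // initial membrane voltage: resting value plus small uniform jitter
  for (int i = 0; i < n; ++i) v[i] = vr + (unif_rand() * 10.0 - 5.0);

  // per-target adjacency list of sources, split by source sign
  std::vector<std::vector<int>> targets(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (adj(i, j)) targets[j].push_back(i);

  // ring buffer of pending synaptic arrivals (per delivery step)
  const int ring = dsteps + 1;
  std::vector<std::vector<double>> pendE(ring, std::vector<double>(n, 0.0)),
      pendI(ring, std::vector<double>(n, 0.0));

  std::vector<int> spk_neuron;
  std::vector<double> spk_time;
  std::vector<int> n_ext(n, 0);
  spk_neuron.reserve(100000);
  spk_time.reserve(100000);

  const int nrec = record_v_ids.size();
  long nrec_steps = nrec > 0 ? nsteps / record_every + 1 : 0;
  NumericMatrix vtrace(nrec > 0 ? nrec_steps : 0, nrec);
  long rec_row = 0;

  Deriv k1, k2, k3, k4;
  for (long step = 0; step < nsteps; ++step) {
    const int slot = (int)(step % ring);

    for (int i = 0; i < n; ++i) {
      // due synaptic arrivals enter the filters at the start of the step
      if (pendE[slot][i] != 0.0) { aE[i] += pendE[slot][i]; pendE[slot][i] = 0.0; }
      if (pendI[slot][i] != 0.0) { aI[i] += pendI[slot][i]; pendI[slot][i] = 0.0; }
      // external Poisson drive: excitatory event, no depression, no delay
      if (p_ext > 0.0 && unif_rand() < p_ext) { aE[i] += gE; ++n_ext[i]; }
    }

    for (int i = 0; i < n; ++i) {
      const double v0 = v[i], w0 = w[i], aE0 = aE[i], sE0 = sE[i],
                   aI0 = aI[i], sI0 = sI[i];
      deriv(v0, w0, aE0, sE0, aI0, sI0, Kv, vr, vt, tauv, Kw, tauw, tauE,
            tauI, i_ext, k1);
      deriv(v0 + 0.5 * dt * k1.dv, w0 + 0.5 * dt * k1.dw,
            aE0 + 0.5 * dt * k1.daE, sE0 + 0.5 * dt * k1.dsE,
            aI0 + 0.5 * dt * k1.daI, sI0 + 0.5 * dt * k1.dsI, Kv, vr, vt,
            tauv, Kw, tauw, tauE, tauI, i_ext, k2);
      deriv(v0 + 0.5 * dt * k2.dv, w0 + 0.5 * dt * k2.dw,
            aE0 + 0.5 * dt * k2.daE, sE0 + 0.5 * dt * k2.dsE,
            aI0 + 0.5 * dt * k2.daI, sI0 + 0.5 * dt * k2.dsI, Kv, vr, vt,
            tauv, Kw, tauw, tauE, tauI, i_ext, k3);
      deriv(v0 + dt * k3.dv, w0 + dt * k3.dw, aE0 + dt * k3.daE,
            sE0 + dt * k3.dsE, aI0 + dt * k3.daI, sI0 + dt * k3.dsI, Kv, vr,
            vt, tauv, Kw, tauw, tauE, tauI, i_ext, k4);
      v[i] = v0 + dt / 6.0 * (k1.dv + 2 * k2.dv + 2 * k3.dv + k4.dv);
      w[i] = w0 + dt / 6.0 * (k1.dw + 2 * k2.dw + 2 * k3.dw + k4.dw);
      aE[i] = aE0 + dt / 6.0 * (k1.daE + 2 * k2.daE + 2 * k3.daE + k4.daE);
      sE[i] = sE0 + dt / 6.0 * (k1.dsE + 2 * k2.dsE + 2 * k3.dsE + k4.dsE);
      aI[i] = aI0 + dt / 6.0 * (k1.daI + 2 * k2.daI + 2 * k3.daI + k4.daI);
      sI[i] = sI0 + dt / 6.0 * (k1.dsI + 2 * k2.dsI + 2 * k3.dsI + k4.dsI);
      if (noise_amp > 0.0) v[i] += noise_amp * norm_rand();
      // flush decayed filter states to zero (avoids denormal slowdown)
      if (aE[i] < 1e-12 && aE[i] > -1e-12) aE[i] = 0.0;
      if (sE[i] < 1e-12 && sE[i] > -1e-12) sE[i] = 0.0;
      if (aI[i] < 1e-12 && aI[i] > -1e-12) aI[i] = 0.0;
      if (sI[i] < 1e-12 && sI[i] > -1e-12) sI[i] = 0.0;
      // neurotransmitter pool relaxes toward 1 with time constant tau_D
      D[i] = 1.0 + (D[i] - 1.0) * d_relax;
    }

    const double t_now = (step + 1) * dt;
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(v[i]))
        stop("non-finite membrane potential at step %ld (neuron %d)",
             step, i + 1);
      if (v[i] >= vp) {
        spk_neuron.push_back(i + 1);
        spk_time.push_back(t_now);
        v[i] = vc;
        w[i] += dw_inc;
        // schedule alpha-function input on every postsynaptic target,
        // amplitude g_S * D read before depletion, signed by source label
        const double amp = (inhibitory[i] ? gI : gE) * D[i];
        const int dslot = (int)((step + dsteps) % ring);
        const std::vector<int> &tg = targets[i];
        if (inhibitory[i])
          for (size_t m = 0; m < tg.size(); ++m) pendI[dslot][tg[m]] += amp;
        else
          for (size_t m = 0; m < tg.size(); ++m) pendE[dslot][tg[m]] += amp;
        D[i] *= alpha;
      }
    }

    if (nrec > 0 && step % record_every == 0) {
      for (int m = 0; m < nrec; ++m)
        vtrace(rec_row, m) = v[record_v_ids[m] - 1];
      ++rec_row;
    }
  }

  List out = List::create(_["neuron"] = wrap(spk_neuron),
                          _["time"] = wrap(spk_time),
                          _["n_ext_events"] = wrap(n_ext));
  if (nrec > 0) out["v_trace"] = vtrace(Range(0, rec_row - 1), Range(0, nrec - 1));
  return out;
}
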