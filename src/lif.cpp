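#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire sweep family under a square current-step protocol.
//
// State equation (units: mV, pA, MOhm, pF, ms):
//   C_m dV/dt = -(V - E_L)/R_m + I(t)
// Within each sampling interval the input is constant, so the membrane
// equation is integrated with the exact exponential update
//   V(t + dt) = V_inf + (V - V_inf) * exp(-dt / tau),  V_inf = E_L + I R_m,
// and threshold crossings are located in continuous time by inverting the
// exponential. This keeps simulated inter-spike intervals equal to the
// closed form t_ref' + tau * log((V_inf - V_reset)/(V_inf - V_th)) to
// machine precision; only the rendering of the trace is quantized to the
// sampling grid.
//
// A spike is rendered as a stereotyped 2 ms waveform (linear rise to +30 mV
// over 0.5 ms, linear decay to V_reset over 1.5 ms) pasted into the trace so
// that waveform-based measures have something to measure. Integration
// resumes from V_reset after a dead time of max(t_ref, 2 ms) (the waveform
// occupies the trace for 2 ms). Gaussian noise of sd `noise_sd` (mV) is
// added to the recorded samples only (measurement noise); the dynamics stay
// deterministic, so ground-truth spike times do not depend on the noise
// draw.
//
// [[Rcpp::export]]
List lif_integrate(NumericVector currents_pA,
                   double rm_mohm, double cm_pf, double el_mv,
                   double vth_mv, double vreset_mv, double tref_ms,
                   double noise_sd_mv,
                   int n_base, int n_step, int n_post, double dt_ms) {
  const int n_sweeps = currents_pA.size();
  const int n_total = n_base + n_step + n_post;
  const double tau_ms = rm_mohm * cm_pf / 1000.0;

  const double wave_ms = 2.0, rise_ms = 0.5, peak_mv = 30.0;
  const double dead_ms = std::max(tref_ms, wave_ms);

  NumericMatrix sweeps(n_total, n_sweeps);
  List spike_times(n_sweeps);

  // waveform voltage at time `u` (ms) after the spike
  auto wave = [&](double u) {
    if (u <= rise_ms) return vth_mv + (peak_mv - vth_mv) * u / rise_ms;
    return peak_mv + (vreset_mv - peak_mv) * (u - rise_ms) / (wave_ms - rise_ms);
  };

  for (int s = 0; s < n_sweeps; ++s) {
    const double amp = currents_pA[s];
    std::vector<double> st;
    double v = el_mv;
    int i = 0;
    while (i < n_total) {
      sweeps(i, s) = v;
      const double inj = (i >= n_base && i < n_base + n_step) ? amp : 0.0;
      const double vinf = el_mv + inj * rm_mohm * 1e-3;
      const double vnext = vinf + (v - vinf) * std::exp(-dt_ms / tau_ms);
      if (v < vth_mv && vinf > vth_mv && vnext >= vth_mv) {
        // exact crossing inside (T_i, T_{i+1}]
        const double off = tau_ms * std::log((vinf - v) / (vinf - vth_mv));
        const double t_spike = i * dt_ms + off;
        st.push_back(t_spike);
        const double t_resume = t_spike + dead_ms;
        int i_res = (int)std::ceil(t_resume / dt_ms);
        // render waveform / reset into the samples covered by the dead time
        for (int k = i + 1; k < i_res && k < n_total; ++k) {
          const double u = k * dt_ms - t_spike;
          sweeps(k, s) = (u < wave_ms) ? wave(u) : vreset_mv;
        }
        if (i_res >= n_total) break;
        // partial segment from t_resume to the next sample time
        const double rem = i_res * dt_ms - t_resume;
        const double inj2 = (i_res - 1 >= n_base && i_res - 1 < n_base + n_step)
                              ? amp : 0.0;
        const double vinf2 = el_mv + inj2 * rm_mohm * 1e-3;
        v = vinf2 + (vreset_mv - vinf2) * std::exp(-rem / tau_ms);
        if (v >= vth_mv) v = vth_mv - 1e-9;  // sub-sample re-crossing guard
        i = i_res;
      } else {
        v = vnext;
        ++i;
      }
    }
    spike_times[s] = wrap(st);
  }

  if (noise_sd_mv > 0.0) {
    RNGScope scope;
    for (int s = 0; s < n_sweeps; ++s)
      for (int i = 0; i < n_total; ++i)
        sweeps(i, s) += R::norm_rand() * noise_sd_mv;
  }

  return List::create(_["sweeps"] = sweeps, _["spike_times_ms"] = spike_times);
}
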