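#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Three-point pyramidal cell: point 1 = soma/axon initial segment, point 2 =
// proximal dendrites, point 3 = distal dendrites. Excitation (feedforward,
// recurrent, noise) lands on point 3; global shunting inhibition on points 1
// and 2. Linear membrane at each point,
//   tau dV/dt = -(V - Vrest) + Rin * (g*(Vrev - V) + I_axial)
// integrated with classical RK4; synaptic conductances are rectangular pulses
// held piecewise-constant within a step.

struct Params {
  double tau, r1, r2, r3, ra;
  double v_rest, v_thresh, v_rev_exc, v_rev_inh;
  double exc_delay, inh_delay, epsc_dur, ipsc_dur, ipsc_g;
  double ap_peak, ahp, refractory;
};

static inline void deriv(const Params &P, double v1, double v2, double v3,
                         double g3_uS, double gi_uS,
                         double &d1, double &d2, double &d3) {
  d1 = (-(v1 - P.v_rest) +
        P.r1 * (gi_uS * (P.v_rev_inh - v1) + (v2 - v1) / P.ra)) / P.tau;
  d2 = (-(v2 - P.v_rest) +
        P.r2 * (gi_uS * (P.v_rev_inh - v2) +
                ((v1 - v2) + (v3 - v2)) / P.ra)) / P.tau;
  d3 = (-(v3 - P.v_rest) +
        P.r3 * (g3_uS * (P.v_rev_exc - v3) + (v2 - v3) / P.ra)) / P.tau;
}

// [[Rcpp::export]]
List cpp_run_trial(int n, IntegerVector offsets, IntegerVector targets,
                   NumericVector amps_nS, NumericVector g_in_nS,
                   double duration_ms, double dt_ms,
                   double inhibition_scale, double excitation_scale,
                   double noise_amplitude, bool noise_input_specific,
                   bool noise_nonspecific, double noise_g_nS,
                   double p_on, double p_off, double input_specific_frac,
                   bool record_raster, NumericVector v_init,
                   NumericVector par, int monitor_cell) {
  Params P;
  P.tau = par["tau_m_ms"];
  P.r1 = par["r_in_soma_Mohm"];
  P.r2 = par["r_in_proximal_Mohm"];
  P.r3 = par["r_in_distal_Mohm"];
  P.ra = par["r_axial_Mohm"];
  P.v_rest = par["v_rest_mV"];
  P.v_thresh = par["v_threshold_mV"];
  P.v_rev_exc = par["v_rev_exc_mV"];
  P.v_rev_inh = par["v_rev_inh_mV"];
  P.exc_delay = par["exc_delay_ms"];
  P.inh_delay = par["inh_delay_ms"];
  P.epsc_dur = par["epsc_duration_ms"];
  P.ipsc_dur = par["ipsc_duration_ms"];
  P.ipsc_g = par["ipsc_g_nS"];
  P.ap_peak = par["ap_peak_mV"];
  P.ahp = par["ahp_mV"];
  P.refractory = par["refractory_ms"];

  const int steps = (int)std::lround(duration_ms / dt_ms);
  const int d_exc = (int)std::lround(P.exc_delay / dt_ms);
  const int d_inh = (int)std::lround(P.inh_delay / dt_ms);
  const int dur_e = (int)std::lround(P.epsc_dur / dt_ms);
  const int dur_i = (int)std::lround(P.ipsc_dur / dt_ms);
  const int refr = (int)std::lround(P.refractory / dt_ms);
  const int per_ms = std::max(1, (int)std::lround(1.0 / dt_ms));
  const int n_ms = (int)std::ceil(duration_ms);

  std::vector<double> v1(n), v2(n), v3(n);
  double i1 = P.v_rest, i2 = P.v_rest, i3 = P.v_rest;
  if (v_init.size() == 3) { i1 = v_init[0]; i2 = v_init[1]; i3 = v_init[2]; }
  for (int i = 0; i < n; ++i) { v1[i] = i1; v2[i] = i2; v3[i] = i3; }

  std::vector<double> g_exc(n, 0.0);       // recurrent conductance, nS
  std::vector<double> ff_mult(n, 1.0);     // input-specific noise multiplier
  std::vector<unsigned char> tele(n, 0);   // telegraph noise state
  std::vector<int> refr_until(n, -1);
  std::vector<unsigned char> ap_flag(n, 0);
  std::vector<int> spike_count(n, 0);

  double noise_on_steps = 0.0;
  long long total_spikes = 0, exc_events = 0;

  // per-trial noise draws
  if (noise_input_specific && noise_amplitude > 0) {
    for (int i = 0; i < n; ++i) {
      double s = unif_rand() < 0.5 ? 1.0 : -1.0;
      ff_mult[i] = 1.0 + s * input_specific_frac * noise_amplitude;
    }
  }
  const double p_init = p_on / (p_on + p_off);
  if (noise_nonspecific && noise_amplitude > 0) {
    for (int i = 0; i < n; ++i) tele[i] = unif_rand() < p_init ? 1 : 0;
  }

  // rectangular-pulse onset/offset deltas in a ring of step buckets
  const int ring = d_exc + dur_e + 2;
  std::vector<std::vector<std::pair<int, double> > > bucket(ring);
  std::vector<int> spikes_at(steps, 0);  // network spikes per step (for inhibition)

  IntegerMatrix raster(record_raster ? n : 1, record_raster ? n_ms : 1);
  NumericVector vmon(monitor_cell >= 0 ? steps : 0);

  const double exc_gain = excitation_scale;
  const double inh_g_per_spike = P.ipsc_g * inhibition_scale; // nS
  double inh_count = 0.0;  // spikes currently driving IPSCs

  for (int t = 0; t < steps; ++t) {
    // apply scheduled recurrent conductance deltas
    std::vector<std::pair<int, double> > &b = bucket[t % ring];
    for (size_t q = 0; q < b.size(); ++q) g_exc[b[q].first] += b[q].second;
    b.clear();

    // global inhibition window: spikes from step t-d_inh enter, spikes from
    // step t-d_inh-dur_i leave
    int s_on = t - d_inh, s_off = t - d_inh - dur_i;
    if (s_on >= 0) inh_count += spikes_at[s_on];
    if (s_off >= 0) inh_count -= spikes_at[s_off];
    const double gi_uS = inh_g_per_spike * inh_count / 1000.0;

    // telegraph noise updated on the 1 ms grid
    if (noise_nonspecific && noise_amplitude > 0 && t % per_ms == 0) {
      for (int i = 0; i < n; ++i) {
        double u = unif_rand();
        if (tele[i]) { if (u < p_off) tele[i] = 0; }
        else if (u < p_on) tele[i] = 1;
      }
    }

    const int ms_bin = t / per_ms;

    for (int i = 0; i < n; ++i) {
      if (ap_flag[i]) {  // one-step AP marker, then afterhyperpolarization
        v1[i] = P.ahp;
        ap_flag[i] = 0;
      }
      double g3 = g_in_nS[i] * ff_mult[i] + g_exc[i] * exc_gain;
      if (tele[i]) { g3 += noise_g_nS * noise_amplitude; noise_on_steps += 1.0; }
      if (g3 < 0) g3 = 0;
      const double g3u = g3 / 1000.0;

      double a1, a2, a3, b1, b2, b3, c1, c2, c3, e1, e2, e3;
      const double h = dt_ms;
      deriv(P, v1[i], v2[i], v3[i], g3u, gi_uS, a1, a2, a3);
      deriv(P, v1[i] + 0.5 * h * a1, v2[i] + 0.5 * h * a2,
            v3[i] + 0.5 * h * a3, g3u, gi_uS, b1, b2, b3);
      deriv(P, v1[i] + 0.5 * h * b1, v2[i] + 0.5 * h * b2,
            v3[i] + 0.5 * h * b3, g3u, gi_uS, c1, c2, c3);
      deriv(P, v1[i] + h * c1, v2[i] + h * c2, v3[i] + h * c3,
            g3u, gi_uS, e1, e2, e3);
      v1[i] += h / 6.0 * (a1 + 2 * b1 + 2 * c1 + e1);
      v2[i] += h / 6.0 * (a2 + 2 * b2 + 2 * c2 + e2);
      v3[i] += h / 6.0 * (a3 + 2 * b3 + 2 * c3 + e3);

      if (v1[i] >= P.v_thresh && t >= refr_until[i]) {
        ++spike_count[i];
        ++total_spikes;
        ++spikes_at[t];
        if (record_raster) ++raster(i, ms_bin < n_ms ? ms_bin : n_ms - 1);
        refr_until[i] = t + refr;
        ap_flag[i] = 1;
        v1[i] = P.ap_peak;
        const int on = (t + d_exc) % ring, off = (t + d_exc + dur_e) % ring;
        for (int e = offsets[i]; e < offsets[i + 1]; ++e) {
          bucket[on].push_back(std::make_pair(targets[e], amps_nS[e]));
          bucket[off].push_back(std::make_pair(targets[e], -amps_nS[e]));
          ++exc_events;
        }
      }
      if (monitor_cell == i) vmon[t] = v1[i];
    }
  }

  NumericMatrix vm(n, 3);
  for (int i = 0; i < n; ++i) { vm(i, 0) = v1[i]; vm(i, 1) = v2[i]; vm(i, 2) = v3[i]; }

  List out = List::create(
      _["spike_count"] = IntegerVector(spike_count.begin(), spike_count.end()),
      _["vm"] = vm,
      _["total_spikes"] = (double)total_spikes,
      _["exc_events"] = (double)exc_events,
      _["inh_compartment_events"] = 2.0 * (double)n * (double)total_spikes,
      _["noise_on_fraction"] =
          (noise_nonspecific && noise_amplitude > 0)
              ? noise_on_steps / ((double)n * (double)steps) : NA_REAL);
  if (record_raster) out["raster"] = raster;
  if (monitor_cell >= 0) out["v_soma_monitor"] = vmon;
  return out;
}
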