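// Time-stepped simulator for networks of escape-noise leaky
// integrate-and-fire neurons with conductance-based (exponential-decay) or
// rectangular current-pulse synapses, axonal delays, absolute refractoriness
// and Tsodyks-Markram short-term plasticity.
//
// Conventions: units mV / ms / nS / pF / pA; one step = dt ms; a spike in
// step s is stamped at the end of the step; synaptic events fired in step s
// act on the target's membrane from step s + delay_steps on.  The RNG is a
// seeded mt19937_64; during an optional preparatory phase a separate seed is
// used and the generator is re-seeded with the main seed at t = 0, so the
// realized initial state depends only on the preparatory seed.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Delivery {
  int post;
  int kind;  // 0 = exc conductance, 1 = inh conductance, 2 = current
  double amt;
};

inline double runif53(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

}  // namespace

// [[Rcpp::export]]
List sim_core_run(List neurons, List synapses, List input_spec,
                  double tau_e, double tau_i,
                  double thr_mod_amp, double thr_mod_period,
                  double dt, int n_steps, int prep_steps,
                  double seed_prep, double seed_main,
                  bool record_potentials, bool init_uniform) {
  NumericVector g_leak = neurons["g_leak"], C_m = neurons["C_m"],
                E_rest = neurons["E_rest"], E_exc = neurons["E_exc"],
                E_inh = neurons["E_inh"], r0 = neurons["r0"],
                V_T = neurons["V_T"], dV = neurons["dV"],
                r_max = neurons["r_max"], refr = neurons["refractory_abs"],
                bias = neurons["bias_current"];
  IntegerVector is_inh = neurons["is_inhibitory"],
                is_input = neurons["is_input"];
  const int n = g_leak.size();

  IntegerVector s_pre = synapses["pre"], s_post = synapses["post"],
                s_kind = synapses["kind"], s_delay = synapses["delay_steps"],
                s_pulse = synapses["pulse_steps"], s_stp = synapses["has_stp"];
  NumericVector s_w = synapses["weight"], s_U = synapses["U"],
                s_D = synapses["D"], s_F = synapses["F"];
  const int ns = s_pre.size();

  // CSR of outgoing synapses by presynaptic neuron
  std::vector<int> out_off(n + 1, 0), out_idx(ns);
  for (int j = 0; j < ns; ++j) out_off[s_pre[j] + 1]++;
  for (int i = 0; i < n; ++i) out_off[i + 1] += out_off[i];
  {
    std::vector<int> cur(out_off.begin(), out_off.end() - 1);
    for (int j = 0; j < ns; ++j) out_idx[cur[s_pre[j]]++] = j;
  }

  // delivery ring buffer
  int horizon = 2;
  for (int j = 0; j < ns; ++j) {
    int h = s_delay[j] + (s_kind[j] == 1 ? s_pulse[j] : 0) + 2;
    if (h > horizon) horizon = h;
  }
  std::vector<std::vector<Delivery>> ring(horizon);

  // input members: neuron id, piecewise CSR (in steps) + optional periodic
  IntegerVector in_neuron = input_spec["neuron"];
  IntegerVector pw_off = input_spec["pw_off"];       // CSR into pw arrays
  IntegerVector pw_break = input_spec["pw_break"];   // segment start steps
  NumericVector pw_rate = input_spec["pw_rate"];
  IntegerVector per_id = input_spec["per_id"];       // -1 or periodic table
  IntegerVector per_start = input_spec["per_start"]; // step periodic takes over
  IntegerVector pt_off = input_spec["pt_off"];       // CSR of periodic tables
  NumericVector pt_rate = input_spec["pt_rate"];     // rate per step in period
  const int n_in = in_neuron.size();
  std::vector<int> pw_ptr(n_in, 0);
  std::vector<double> in_p(n_in, 0.0), in_rate_cur(n_in, -1.0);

  // state
  std::vector<double> V(n), g_e(n, 0.0), g_i(n, 0.0), I_rect(n, 0.0);
  std::vector<int> refr_cnt(n, 0), refr_steps(n);
  std::vector<double> stp_u(ns, 0.0), stp_R(ns, 1.0), stp_tlast(ns, 0.0);
  std::vector<uint8_t> stp_seen(ns, 0);
  for (int i = 0; i < n; ++i) refr_steps[i] = (int)std::lround(refr[i] / dt);

  std::mt19937_64 rng(prep_steps > 0 ? (uint64_t)seed_prep
                                     : (uint64_t)seed_main);
  for (int i = 0; i < n; ++i)
    V[i] = init_uniform ? E_rest[i] + (V_T[i] - E_rest[i]) * runif53(rng)
                        : E_rest[i];

  const double dec_e = std::exp(-dt / tau_e), dec_i = std::exp(-dt / tau_i);
  const double prep_dur = prep_steps * dt;

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  int rec_steps = record_potentials ? (n_steps - prep_steps) : 0;
  NumericMatrix Vrec(rec_steps > 0 ? rec_steps : 1,
                     rec_steps > 0 ? n : 1);

  for (int s = 0; s < n_steps; ++s) {
    if (s == prep_steps) rng.seed((uint64_t)seed_main);
    const double t_end = (s + 1) * dt - prep_dur;
    double thr_off = 0.0;
    if (thr_mod_period > 0.0)
      thr_off = thr_mod_amp * std::sin(2.0 * M_PI * t_end / thr_mod_period);

    // 1. due deliveries
    std::vector<Delivery> &bucket = ring[s % horizon];
    for (const Delivery &d : bucket) {
      if (d.kind == 0) g_e[d.post] += d.amt;
      else if (d.kind == 1) g_i[d.post] += d.amt;
      else I_rect[d.post] += d.amt;
    }
    bucket.clear();

    // 2. membrane + spiking
    for (int i = 0; i < n; ++i) {
      bool spiked = false;
      if (is_input[i]) {
        // external Poisson input neuron: rate from its step function
        continue;  // handled in the input loop below
      }
      if (refr_cnt[i] > 0) {
        refr_cnt[i]--;
        V[i] = E_rest[i];
      } else {
        const double gt = g_leak[i] + g_e[i] + g_i[i];
        const double Vinf = (g_leak[i] * E_rest[i] + g_e[i] * E_exc[i] +
                             g_i[i] * E_inh[i] + I_rect[i] + bias[i]) / gt;
        V[i] = Vinf + (V[i] - Vinf) * std::exp(-dt * gt / C_m[i]);
        double r = r0[i] * std::exp((V[i] - V_T[i] - thr_off) / dV[i]);
        if (r > r_max[i]) r = r_max[i];
        const double p = -std::expm1(-r * dt);
        if (runif53(rng) < p) spiked = true;
      }
      if (spiked) {
        sp_id.push_back(i + 1);
        sp_t.push_back(t_end);
        refr_cnt[i] = refr_steps[i];
        V[i] = E_rest[i];
        for (int jj = out_off[i]; jj < out_off[i + 1]; ++jj) {
          const int j = out_idx[jj];
          double A = s_w[j];
          if (s_stp[j]) {
            if (!stp_seen[j]) {
              stp_u[j] = s_U[j]; stp_R[j] = 1.0; stp_seen[j] = 1;
            } else {
              const double del = t_end - stp_tlast[j];
              const double u_new = s_U[j] + stp_u[j] * (1.0 - s_U[j]) *
                                   std::exp(-del / s_F[j]);
              const double R_new = 1.0 + (stp_R[j] * (1.0 - stp_u[j]) - 1.0) *
                                   std::exp(-del / s_D[j]);
              stp_u[j] = u_new; stp_R[j] = R_new;
            }
            stp_tlast[j] = t_end;
            A *= stp_u[j] * stp_R[j];
          }
          const int post = s_post[j];
          if (s_kind[j] == 0) {
            ring[(s + s_delay[j]) % horizon].push_back(
              {post, is_inh[i] ? 1 : 0, A});
          } else {
            const double amt = (is_inh[i] ? -A : A);
            ring[(s + s_delay[j]) % horizon].push_back({post, 2, amt});
            ring[(s + s_delay[j] + s_pulse[j]) % horizon].push_back(
              {post, 2, -amt});
          }
        }
      }
    }

    // 3. input neurons (Poisson from step functions)
    for (int m = 0; m < n_in; ++m) {
      const int i = in_neuron[m];
      double rate;
      if (per_id[m] >= 0 && s >= per_start[m]) {
        const int tb = per_id[m];
        const int plen = pt_off[tb + 1] - pt_off[tb];
        rate = pt_rate[pt_off[tb] + (s - per_start[m]) % plen];
      } else {
        while (pw_ptr[m] + 1 < pw_off[m + 1] - pw_off[m] &&
               pw_break[pw_off[m] + pw_ptr[m] + 1] <= s)
          pw_ptr[m]++;
        rate = (pw_off[m + 1] > pw_off[m])
                 ? pw_rate[pw_off[m] + pw_ptr[m]] : 0.0;
      }
      if (rate != in_rate_cur[m]) {
        in_rate_cur[m] = rate;
        in_p[m] = -std::expm1(-rate * dt);
      }
      if (refr_cnt[i] > 0) { refr_cnt[i]--; continue; }
      if (in_p[m] > 0.0 && runif53(rng) < in_p[m]) {
        sp_id.push_back(i + 1);
        sp_t.push_back(t_end);
        refr_cnt[i] = refr_steps[i];
        for (int jj = out_off[i]; jj < out_off[i + 1]; ++jj) {
          const int j = out_idx[jj];
          double A = s_w[j];
          if (s_stp[j]) {
            if (!stp_seen[j]) {
              stp_u[j] = s_U[j]; stp_R[j] = 1.0; stp_seen[j] = 1;
            } else {
              const double del = t_end - stp_tlast[j];
              const double u_new = s_U[j] + stp_u[j] * (1.0 - s_U[j]) *
                                   std::exp(-del / s_F[j]);
              const double R_new = 1.0 + (stp_R[j] * (1.0 - stp_u[j]) - 1.0) *
                                   std::exp(-del / s_D[j]);
              stp_u[j] = u_new; stp_R[j] = R_new;
            }
            stp_tlast[j] = t_end;
            A *= stp_u[j] * stp_R[j];
          }
          const int post = s_post[j];
          if (s_kind[j] == 0) {
            ring[(s + s_delay[j]) % horizon].push_back(
              {post, is_inh[i] ? 1 : 0, A});
          } else {
            const double amt = (is_inh[i] ? -A : A);
            ring[(s + s_delay[j]) % horizon].push_back({post, 2, amt});
            ring[(s + s_delay[j] + s_pulse[j]) % horizon].push_back(
              {post, 2, -amt});
          }
        }
      }
    }

    // 4. conductance decay
    for (int i = 0; i < n; ++i) {
      g_e[i] *= dec_e;
      g_i[i] *= dec_i;
    }

    if (record_potentials && s >= prep_steps) {
      const int row = s - prep_steps;
      for (int i = 0; i < n; ++i) Vrec(row, i) = V[i];
    }
  }

  List out = List::create(
    _["neuron_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["time_ms"] = NumericVector(sp_t.begin(), sp_t.end()));
  if (record_potentials) out["potentials"] = Vrec;
  return out;
}
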