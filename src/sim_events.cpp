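// Event-driven simulator for networks whose synapses are rectangular
// current pulses.  Because the membrane responds quasi-statically to a
// piecewise-constant input current, the membrane potential of every neuron
// is piecewise constant between events, the escape hazard is piecewise
// constant, and sampling the next spike with a fresh exponential waiting
// time after every potential change is exact (memorylessness).  This is the
// backend used for WTA constraint-satisfaction networks, where it tracks an
// online decoding of the network's tentative solution on a regular check
// grid and can stop at the first time the full solution is reached.

#include <Rcpp.h>
#include <random>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Ev {
  double t;
  int type;  // 0 spike candidate, 1 delivery-on, 2 delivery-off, 3 refr end
  int a;     // neuron (0,2,3) or synapse (1)
  int b;     // version for spike candidates
  double amp;
  bool operator>(const Ev &o) const { return t > o.t; }
};

inline double runif53(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

}  // namespace

// [[Rcpp::export]]
List sim_events_run(NumericVector V_base, NumericVector r0, NumericVector V_T,
                    NumericVector dV, NumericVector r_max, NumericVector refr,
                    IntegerVector syn_off, IntegerVector syn_target,
                    NumericVector syn_amp, NumericVector syn_delay,
                    NumericVector syn_pulse,
                    IntegerVector syn_stp, NumericVector syn_U,
                    NumericVector syn_D, NumericVector syn_F,
                    LogicalVector record_mask,
                    IntegerVector cell_field, IntegerVector cell_digit,
                    IntegerVector correct_digit, int n_fields, int n_digits,
                    double tau, double check_dt, bool stop_on_solve,
                    double duration, double seed) {
  const int n = V_base.size();
  std::vector<double> V(V_base.begin(), V_base.end());
  std::vector<double> refr_end(n, -1e300);
  std::vector<int> version(n, 0);
  std::mt19937_64 rng((uint64_t)seed);

  std::priority_queue<Ev, std::vector<Ev>, std::greater<Ev>> q;

  auto rate_of = [&](int i) {
    double r = r0[i] * std::exp((V[i] - V_T[i]) / dV[i]);
    return r > r_max[i] ? r_max[i] : r;
  };
  const double horizon_slack = 1.0;
  auto resample = [&](int i, double t) {
    if (t < refr_end[i]) return;  // resampled at refractory end
    const double r = rate_of(i);
    version[i]++;
    if (r <= 0.0) return;
    const double w = -std::log(1.0 - runif53(rng)) / r;
    // a candidate beyond the run horizon can never fire before a further
    // potential change re-samples it; skip the heap push
    if (t + w > duration + horizon_slack) return;
    q.push({t + w, 0, i, version[i], 0.0});
  };

  // Tsodyks-Markram state per dynamic synapse
  const int ns = syn_target.size();
  std::vector<double> stp_u(ns, 0.0), stp_R(ns, 1.0), stp_tlast(ns, 0.0);
  std::vector<uint8_t> stp_seen(ns, 0);

  const bool track = n_fields > 0;
  std::vector<double> last(track ? n_fields * n_digits : 0, -1e300);

  std::vector<int> sp_id;
  std::vector<double> sp_t;
  std::vector<double> perf;
  double solve_time = NA_REAL;

  for (int i = 0; i < n; ++i) resample(i, 0.0);
  double next_check = check_dt > 0 ? check_dt : 2.0 * duration + 1.0;

  while (!q.empty()) {
    Ev ev = q.top();
    // run decode checks due before the next event (or end of run)
    while (track && next_check <= duration + 1e-12 &&
           next_check <= ev.t) {
      const double t = next_check;
      int n_corr = 0;
      for (int f = 0; f < n_fields; ++f) {
        const int c = correct_digit[f];
        if (c < 0) continue;
        bool ok = (t - last[f * n_digits + c] < tau) &&
                  (last[f * n_digits + c] <= t);
        if (ok) {
          for (int d = 0; d < n_digits; ++d) {
            if (d == c) continue;
            if (t - last[f * n_digits + d] < tau) { ok = false; break; }
          }
        }
        if (ok) n_corr++;
      }
      const double p = (double)n_corr / (double)n_fields;
      perf.push_back(p);
      if (p >= 1.0 && !R_finite(solve_time)) {
        solve_time = t;
        if (stop_on_solve) goto done;
      }
      next_check += check_dt;
    }
    if (ev.t > duration) break;
    q.pop();
    switch (ev.type) {
      case 0: {  // spike candidate
        const int i = ev.a;
        if (ev.b != version[i] || ev.t < refr_end[i]) break;
        if (record_mask[i]) {
          sp_id.push_back(i + 1);
          sp_t.push_back(ev.t);
        }
        if (track && cell_field[i] >= 0)
          last[cell_field[i] * n_digits + cell_digit[i]] = ev.t;
        version[i]++;
        if (refr[i] > 0.0) {
          refr_end[i] = ev.t + refr[i];
          q.push({refr_end[i], 3, i, 0, 0.0});
        } else {
          resample(i, ev.t);
        }
        for (int j = syn_off[i]; j < syn_off[i + 1]; ++j) {
          double A = syn_amp[j];
          if (syn_stp[j]) {
            if (!stp_seen[j]) {
              stp_u[j] = syn_U[j]; stp_R[j] = 1.0; stp_seen[j] = 1;
            } else {
              const double del = ev.t - stp_tlast[j];
              const double u_new = syn_U[j] + stp_u[j] * (1.0 - syn_U[j]) *
                                   std::exp(-del / syn_F[j]);
              const double R_new = 1.0 +
                (stp_R[j] * (1.0 - stp_u[j]) - 1.0) *
                std::exp(-del / syn_D[j]);
              stp_u[j] = u_new; stp_R[j] = R_new;
            }
            stp_tlast[j] = ev.t;
            A *= stp_u[j] * stp_R[j];   // A_k = w u_k R_k, first = w U
          }
          q.push({ev.t + syn_delay[j], 1, j, 0, A});
        }
        break;
      }
      case 1: {  // delivery on
        const int j = ev.a;
        const int tgt = syn_target[j];
        V[tgt] += ev.amp;
        q.push({ev.t + syn_pulse[j], 2, tgt, 0, ev.amp});
        resample(tgt, ev.t);
        break;
      }
      case 2: {  // delivery off
        V[ev.a] -= ev.amp;
        resample(ev.a, ev.t);
        break;
      }
      case 3: {  // refractory end
        refr_end[ev.a] = -1e300;
        resample(ev.a, ev.t);
        break;
      }
    }
  }
  // remaining checks after the last event
  while (track && next_check <= duration + 1e-12) {
    const double t = next_check;
    int n_corr = 0;
    for (int f = 0; f < n_fields; ++f) {
      const int c = correct_digit[f];
      if (c < 0) continue;
      bool ok = (t - last[f * n_digits + c] < tau) &&
                (last[f * n_digits + c] <= t);
      if (ok) {
        for (int d = 0; d < n_digits; ++d) {
          if (d == c) continue;
          if (t - last[f * n_digits + d] < tau) { ok = false; break; }
        }
      }
      if (ok) n_corr++;
    }
    const double p = (double)n_corr / (double)n_fields;
    perf.push_back(p);
    if (p >= 1.0 && !R_finite(solve_time)) {
      solve_time = t;
      if (stop_on_solve) break;
    }
    next_check += check_dt;
  }
done:
  return List::create(
    _["neuron_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["time_ms"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["perf"] = NumericVector(perf.begin(), perf.end()),
    _["solve_time"] = solve_time);
}
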