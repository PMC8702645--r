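// Euler integration of the sparse E-I QIF network with delta-pulse coupling.
// Neurons 0..Ne-1 are excitatory, Ne..Ne+Ni-1 inhibitory. Spikes detected at a
// finite threshold v_peak are reset to -v_peak and held for a refractory
// interval 2*tau_m/v_peak (the finite-threshold surrogate of the traverse
// through +/-infinity); pulses emitted in one step are delivered at the next.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_simulate_qif(int Ne, int Ni,
                      IntegerVector pre_offsets,   // length N+1, CSR pre -> post
                      IntegerVector pre_targets,   // 0-based post indices
                      NumericVector v0,            // initial potentials, length N
                      double A_ee, double A_ie,    // jump on post e/i from an E spike (>0)
                      double A_ei, double A_ii,    // jump on post e/i from an I spike (>0, applied with minus)
                      double Ie, double Ii,        // sqrt(K)*I0 per population
                      double tau_e, double tau_i,
                      double dt, int n_transient, int n_steps,
                      double v_peak, double hold_ms_e, double hold_ms_i,
                      int trace_stride,            // steps per trace sample
                      int record_v_stride) {       // 0 = do not store per-neuron samples
  const int N = Ne + Ni;
  const int n_total = n_transient + n_steps;
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<int> hold(N, 0);
  std::vector<int> spiked; spiked.reserve(1024);
  const int hold_e = (int)std::lround(hold_ms_e / dt);
  const int hold_i = (int)std::lround(hold_ms_i / dt);

  std::vector<double> sp_t; std::vector<int> sp_id;
  std::vector<long> count(N, 0);   // spikes after transient
  // binned population rates + mean potential traces
  const int n_trace = n_steps / trace_stride;
  NumericMatrix trace(n_trace, 5);  // t_ms, R_e (1/ms), V_e, R_i (1/ms), V_i
  long bin_e = 0, bin_i = 0;
  // optional per-neuron potential samples (post-transient)
  int n_vrow = (record_v_stride > 0) ? n_steps / record_v_stride : 0;
  NumericMatrix vsamp(n_vrow, record_v_stride > 0 ? N : 0);
  int vrow = 0;

  bool blown = false; double t_blow = NA_REAL;
  const double ae = dt / tau_e, ai = dt / tau_i;
  double* vp_ = v.data();
  int* hp_ = hold.data();
  const int* off = pre_offsets.begin();
  const int* tgt = pre_targets.begin();
  for (int n = 0; n < n_total; ++n) {
    const bool measuring = n >= n_transient;
    // deliver pulses emitted at the previous step directly to the targets
    // (held neurons receive none)
    for (size_t m = 0; m < spiked.size(); ++m) {
      const int pre = spiked[m];
      const bool exc = pre < Ne;
      for (int q = off[pre]; q < off[pre + 1]; ++q) {
        const int post = tgt[q];
        if (hp_[post] > 0) continue;
        if (exc) vp_[post] += (post < Ne) ? A_ee : A_ie;
        else     vp_[post] -= (post < Ne) ? A_ei : A_ii;
      }
    }
    spiked.clear();
    for (int j = 0; j < Ne; ++j) {
      if (hp_[j] > 0) { --hp_[j]; continue; }
      double vj = vp_[j];
      vj += ae * (vj * vj + Ie);
      if (vj >= v_peak) {
        spiked.push_back(j);
        if (measuring) { sp_t.push_back((n + 1 - n_transient) * dt); sp_id.push_back(j);
                         ++count[j]; ++bin_e; }
        vj = -v_peak;
        hp_[j] = hold_e;
      }
      vp_[j] = vj;
    }
    for (int j = Ne; j < N; ++j) {
      if (hp_[j] > 0) { --hp_[j]; continue; }
      double vj = vp_[j];
      vj += ai * (vj * vj + Ii);
      if (vj >= v_peak) {
        spiked.push_back(j);
        if (measuring) { sp_t.push_back((n + 1 - n_transient) * dt); sp_id.push_back(j);
                         ++count[j]; ++bin_i; }
        vj = -v_peak;
        hp_[j] = hold_i;
      }
      vp_[j] = vj;
    }
    if (!std::isfinite(vp_[0])) { blown = true; t_blow = (n + 1) * dt; break; }
    if (measuring) {
      const int k = n - n_transient;
      if ((k + 1) % trace_stride == 0) {
        const int row = (k + 1) / trace_stride - 1;
        if (row < n_trace) {
          double se = 0, si = 0; int ce = 0, ci = 0;
          for (int j = 0; j < Ne; ++j) if (hold[j] == 0) { se += v[j]; ++ce; }
          for (int j = Ne; j < N; ++j) if (hold[j] == 0) { si += v[j]; ++ci; }
          trace(row, 0) = (k + 1) * dt;
          trace(row, 1) = (double)bin_e / (trace_stride * dt * Ne);
          trace(row, 2) = ce > 0 ? se / ce : NA_REAL;
          trace(row, 3) = (double)bin_i / (trace_stride * dt * Ni);
          trace(row, 4) = ci > 0 ? si / ci : NA_REAL;
          bin_e = 0; bin_i = 0;
        }
      }
      if (record_v_stride > 0 && (k + 1) % record_v_stride == 0 && vrow < n_vrow) {
        for (int j = 0; j < N; ++j) vsamp(vrow, j) = v[j];
        ++vrow;
      }
    }
    // any remaining finiteness problem across neurons (cheap scan every 1000 steps)
    if (n % 1000 == 999) {
      for (int j = 0; j < N; ++j)
        if (!std::isfinite(v[j])) { blown = true; t_blow = (n + 1) * dt; break; }
      if (blown) break;
    }
  }
  NumericVector spike_t(sp_t.begin(), sp_t.end());
  IntegerVector spike_id(sp_id.begin(), sp_id.end());
  NumericVector counts(N);
  for (int j = 0; j < N; ++j) counts[j] = (double)count[j];
  return List::create(_["spike_t"] = spike_t, _["spike_id"] = spike_id,
                      _["counts"] = counts, _["trace"] = trace,
                      _["v_samples"] = vsamp,
                      _["blown"] = blown, _["t_blowup"] = t_blow,
                      _["v_final"] = NumericVector(v.begin(), v.end()));
}
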