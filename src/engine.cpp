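// Clock-driven network engine: 64-slot delay-buffered spike delivery,
// conductance accumulation, exact-integration membrane updates with
// sub-cycling, and an emulated s16.15 fixed-point arithmetic path.
//
// Conductances are held normalized (g * tau_m / cm, dimensionless); the
// membrane propagator over a sub-cycle h with frozen conductances is
//   v_inf = (v_rest + ge*Ee + gi*Ei + ihat) / (1 + ge + gi)
//   v    <- v_inf + (v - v_inf) * exp(-h * (1 + ge + gi) / tau_m)
// Threshold/reset/refractoriness are resolved once per full timestep.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int N_SLOTS = 64;

// s16.15 accum emulation: round to nearest multiple of 2^-15, ties to even,
// saturate at the format bounds (saturations are counted, never silent).
static const double Q15 = 32768.0;            // 2^15
static const double ACC_MAX = (2147483647.0) / Q15; // (2^31 - 1) * 2^-15
static const double Q32 = 4294967296.0;       // 2^32 (u0.32 grid for decays)

static inline double q15(double x, long long &sat) {
  double y = std::nearbyint(x * Q15) / Q15;
  if (y > ACC_MAX) { y = ACC_MAX; ++sat; }
  else if (y < -ACC_MAX) { y = -ACC_MAX; ++sat; }
  return y;
}
// truncating multiply result (integer multiply discards low bits): used for
// the conductance decay so that a geometric decay reaches zero instead of
// stalling on the round-to-nearest grid
static inline double t15(double x, long long &sat) {
  double y = std::trunc(x * Q15) / Q15;
  if (y > ACC_MAX) { y = ACC_MAX; ++sat; }
  else if (y < -ACC_MAX) { y = -ACC_MAX; ++sat; }
  return y;
}
static inline double q32(double x) {
  return std::nearbyint(x * Q32) / Q32;
}

// par columns per type: cm, i_offset, tau_m, tau_refract, tau_syn_e,
// tau_syn_i, v_reset, v_rest, v_thresh, e_rev_e, e_rev_i
// [[Rcpp::export]]
List cpp_run_network(IntegerVector type_of,       // 0-based type per neuron
                     LogicalVector relay_type,    // per type: relay flag
                     NumericMatrix par,           // per-type parameter rows
                     IntegerVector edge_ptr,      // CSR by source (0-based, length n+1)
                     IntegerVector edge_tgt,      // 0-based target ids
                     NumericVector edge_wnorm,    // normalized |weight| (per target type)
                     NumericVector edge_wraw,     // |weight| in uS (for conservation counters)
                     IntegerVector edge_sign,     // +1 excitatory, -1 inhibitory
                     IntegerVector edge_delay,    // steps, 1..64
                     IntegerVector edge_proj,     // 0-based projection index
                     int n_proj,
                     IntegerVector in_id,         // input (relay) spikes, sorted by step
                     IntegerVector in_step,
                     int n_steps, double dt, int n_sc, bool fixed,
                     IntegerVector record_ids) {  // 0-based ids for state traces
  const int n = type_of.size();
  const int n_types = par.nrow();
  const double h = dt / n_sc;

  // per-type constants
  std::vector<double> de(n_types), di(n_types), gl(n_types), ihat(n_types),
      vreset(n_types), vrest(n_types), vthresh(n_types), taum(n_types),
      ee(n_types), ei(n_types);
  std::vector<int> refsteps(n_types);
  for (int k = 0; k < n_types; ++k) {
    if (relay_type[k]) continue;
    double cm = par(k, 0), ioff = par(k, 1), tm = par(k, 2), tref = par(k, 3);
    double tse = par(k, 4), tsi = par(k, 5);
    gl[k] = cm / tm;
    ihat[k] = ioff / gl[k];
    de[k] = std::exp(-h / tse);
    di[k] = std::exp(-h / tsi);
    if (fixed) { de[k] = q32(de[k]); di[k] = q32(di[k]); }
    vreset[k] = par(k, 6); vrest[k] = par(k, 7); vthresh[k] = par(k, 8);
    ee[k] = par(k, 9); ei[k] = par(k, 10);
    taum[k] = tm;
    refsteps[k] = (int)std::floor(tref / dt + 0.5);
  }

  // state
  std::vector<double> v(n), ge(n, 0.0), gi(n, 0.0);
  std::vector<int> refr(n, 0);
  std::vector<char> relay(n);
  for (int i = 0; i < n; ++i) {
    int k = type_of[i];
    relay[i] = relay_type[k] ? 1 : 0;
    v[i] = relay[i] ? 0.0 : vrest[k];
  }

  // delay ring buffers (excitatory / inhibitory channel per neuron)
  std::vector<double> bufE((size_t)n * N_SLOTS, 0.0), bufI((size_t)n * N_SLOTS, 0.0);

  // recording
  const int n_rec = record_ids.size();
  NumericMatrix trace_v(n_rec, n_steps), trace_ge(n_rec, n_steps),
      trace_gi(n_rec, n_steps);
  std::vector<int> rec_slot(n, -1);
  for (int r = 0; r < n_rec; ++r) rec_slot[record_ids[r]] = r;

  std::vector<int> spike_id, spike_step;
  spike_id.reserve(1 << 16); spike_step.reserve(1 << 16);

  long long sat = 0;
  double tot_exc = 0.0, tot_inh = 0.0;
  std::vector<double> proj_events(n_proj, 0.0);
  std::vector<int> fired; fired.reserve(1024);

  int in_pos = 0;
  const int n_in = in_id.size();

  for (int t = 0; t < n_steps; ++t) {
    const int slot = t & (N_SLOTS - 1);
    fired.clear();

    // input (relay) spikes scheduled for this step
    while (in_pos < n_in && in_step[in_pos] == t) {
      int i = in_id[in_pos++];
      spike_id.push_back(i); spike_step.push_back(t);
      fired.push_back(i);
    }

    // neuron updates
    for (int i = 0; i < n; ++i) {
      if (relay[i]) continue;
      const int k = type_of[i];
      const size_t base = (size_t)i * N_SLOTS + slot;
      double incE = bufE[base], incI = bufI[base];
      bufE[base] = 0.0; bufI[base] = 0.0;
      double gE = ge[i], gI = gi[i], vi = v[i];
      if (fixed) {
        if (incE != 0.0) gE = q15(gE + q15(incE, sat), sat);
        if (incI != 0.0) gI = q15(gI + q15(incI, sat), sat);
      } else {
        gE += incE; gI += incI;
      }
      if (refr[i] > 0) {
        // conductances keep decaying; voltage clamped at reset
        if (fixed) {
          for (int s = 0; s < n_sc; ++s) {
            gE = t15(gE * de[k], sat); gI = t15(gI * di[k], sat);
          }
        } else {
          for (int s = 0; s < n_sc; ++s) { gE *= de[k]; gI *= di[k]; }
        }
        --refr[i];
        vi = vreset[k];
      } else {
        for (int s = 0; s < n_sc; ++s) {
          if (fixed) {
            gE = t15(gE * de[k], sat); gI = t15(gI * di[k], sat);
          } else {
            gE *= de[k]; gI *= di[k];
          }
          const double den = 1.0 + gE + gI;
          const double vinf = (vrest[k] + gE * ee[k] + gI * ei[k] + ihat[k]) / den;
          const double prop = std::exp(-h * den / taum[k]);
          // fixed mode: intermediates at register precision (the decay
          // constant itself sits on the u0.32 grid), one rounding on store
          vi = vinf + (vi - vinf) * (fixed ? q32(prop) : prop);
          if (fixed) vi = q15(vi, sat);
        }
        if (vi >= vthresh[k]) {
          spike_id.push_back(i); spike_step.push_back(t);
          fired.push_back(i);
          vi = vreset[k];
          refr[i] = refsteps[k];
        }
      }
      ge[i] = gE; gi[i] = gI; v[i] = vi;
      const int r = rec_slot[i];
      if (r >= 0) {
        trace_v(r, t) = vi;
        trace_ge(r, t) = gE * gl[k];
        trace_gi(r, t) = gI * gl[k];
      }
    }

    // deliver all spikes emitted at t into target buffers at t + delay
    for (size_t f = 0; f < fired.size(); ++f) {
      const int i = fired[f];
      for (int e = edge_ptr[i]; e < edge_ptr[i + 1]; ++e) {
        const int j = edge_tgt[e];
        const int a = (t + edge_delay[e]) & (N_SLOTS - 1);
        const size_t base = (size_t)j * N_SLOTS + a;
        if (edge_sign[e] > 0) { bufE[base] += edge_wnorm[e]; tot_exc += edge_wraw[e]; }
        else                  { bufI[base] += edge_wnorm[e]; tot_inh += edge_wraw[e]; }
        proj_events[edge_proj[e]] += 1.0;
      }
    }
  }

  return List::create(
      _["spike_id"] = IntegerVector(spike_id.begin(), spike_id.end()),
      _["spike_step"] = IntegerVector(spike_step.begin(), spike_step.end()),
      _["trace_v"] = trace_v, _["trace_ge"] = trace_ge, _["trace_gi"] = trace_gi,
      _["delivered_exc"] = tot_exc, _["delivered_inh"] = tot_inh,
      _["saturations"] = (double)sat,
      _["proj_events"] = NumericVector(proj_events.begin(), proj_events.end()));
}

// Per-projection peak of the per-target, per-timestep summed synaptic input
// (uS). Spikes must be sorted by step; every projection has a single delay,
// so arrivals stay step-ordered and a running per-target accumulator per
// projection suffices.
// [[Rcpp::export]]
List cpp_projection_peaks(IntegerVector spk_id, IntegerVector spk_step,
                          IntegerVector edge_ptr, IntegerVector edge_tgt,
                          IntegerVector edge_proj, NumericVector edge_wraw,
                          IntegerVector edge_sign,
                          int n_neurons, int n_proj) {
  std::vector<double> peak(n_proj, 0.0);
  std::vector<std::vector<double> > acc(n_proj, std::vector<double>());
  std::vector<std::vector<int> > touched(n_proj);
  for (int p = 0; p < n_proj; ++p) acc[p].assign(n_neurons, 0.0);

  const int m = spk_id.size();
  int pos = 0;
  while (pos < m) {
    const int t = spk_step[pos];
    int end = pos;
    while (end < m && spk_step[end] == t) ++end;
    for (int s = pos; s < end; ++s) {
      const int i = spk_id[s];
      for (int e = edge_ptr[i]; e < edge_ptr[i + 1]; ++e) {
        const int p = edge_proj[e];
        const int j = edge_tgt[e];
        if (acc[p][j] == 0.0) touched[p].push_back(j);
        acc[p][j] += edge_wraw[e];
      }
    }
    for (int p = 0; p < n_proj; ++p) {
      for (size_t u = 0; u < touched[p].size(); ++u) {
        const int j = touched[p][u];
        if (acc[p][j] > peak[p]) peak[p] = acc[p][j];
        acc[p][j] = 0.0;
      }
      touched[p].clear();
    }
    pos = end;
  }
  return List::create(_["peak"] = NumericVector(peak.begin(), peak.end()));
}

// Multicast packet counting: each source spike contributes one packet to
// every distinct core hosting at least one of its synaptic targets.
// core_ptr/core_ids give the distinct destination core list per neuron.
// Returns per-core maxima of per-timestep received packets, per-core totals,
// and the grand total.
// [[Rcpp::export]]
List cpp_count_packets(IntegerVector spk_id, IntegerVector spk_step,
                       IntegerVector core_ptr, IntegerVector core_ids,
                       int n_cores) {
  std::vector<double> core_max(n_cores, 0.0), core_tot(n_cores, 0.0);
  std::vector<double> cnt(n_cores, 0.0);
  std::vector<int> touched; touched.reserve(n_cores);
  double total = 0.0;

  const int m = spk_id.size();
  int pos = 0;
  while (pos < m) {
    const int t = spk_step[pos];
    int end = pos;
    while (end < m && spk_step[end] == t) ++end;
    for (int s = pos; s < end; ++s) {
      const int i = spk_id[s];
      for (int e = core_ptr[i]; e < core_ptr[i + 1]; ++e) {
        const int c = core_ids[e];
        if (cnt[c] == 0.0) touched.push_back(c);
        cnt[c] += 1.0;
      }
    }
    for (size_t u = 0; u < touched.size(); ++u) {
      const int c = touched[u];
      if (cnt[c] > core_max[c]) core_max[c] = cnt[c];
      core_tot[c] += cnt[c];
      total += cnt[c];
      cnt[c] = 0.0;
    }
    touched.clear();
    pos = end;
  }
  return List::create(_["core_max"] = NumericVector(core_max.begin(), core_max.end()),
                      _["core_total"] = NumericVector(core_tot.begin(), core_tot.end()),
                      _["total"] = total);
}
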