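#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler simulation of recurrent exponential integrate-and-fire
// (EIF) layers driven by an inhomogeneous-Poisson input layer.
//
// Populations are concatenated into one neuron array; per-neuron parameter
// vectors carry the population differences. Connectivity is a CSR edge list
// over global presynaptic indices: input-layer neurons first (0..n_in-1),
// then the EIF neurons (n_in..n_in+n_eif-1). Positive edge weights
// increment the target's excitatory synaptic state, negative weights the
// inhibitory state; the two states decay with tau_e / tau_i and enter the
// membrane equation as currents in mV/ms.
//
// in_rates: n_in x n_bins input rates (Hz), piecewise constant per bin.
// bin_cycle: per bin, the 1-based ON-interval id for spike counting
//   (0 during OFF intervals).
// [[Rcpp::export(name = ".eif_net_sim")]]
List eif_net_sim(NumericMatrix in_rates,
                 double bin_ms,
                 double dt,
                 IntegerVector bin_cycle,
                 int n_cycles,
                 IntegerVector edge_ptr,   // length n_in + n_eif + 1
                 IntegerVector edge_tgt,
                 NumericVector edge_w,
                 NumericVector taum,
                 NumericVector EL,
                 NumericVector VT,
                 NumericVector Vth,
                 NumericVector Vre,
                 NumericVector DeltaT,
                 NumericVector tauref,
                 NumericVector mu,
                 double tau_e,
                 double tau_i,
                 NumericVector V0,
                 double v_floor,
                 NumericVector bg_series,   // per rate-bin common current
                 NumericVector bg_weight) { // per-neuron coupling to it
  const int n_in = in_rates.nrow();
  const int n_bins = in_rates.ncol();
  const int n_eif = taum.size();
  const int steps_per_bin = (int) std::round(bin_ms / dt);
  const long n_steps = (long) n_bins * steps_per_bin;

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> se(n_eif, 0.0), si(n_eif, 0.0);
  std::vector<double> ref(n_eif, 0.0);
  std::vector<double> p_in(n_in, 0.0);
  const double dec_e = std::exp(-dt / tau_e);
  const double dec_i = std::exp(-dt / tau_i);

  IntegerMatrix counts(n_cycles, n_eif);
  std::vector<long> total_spikes(n_eif, 0);
  double v_min = R_PosInf, v_max = R_NegInf;
  long blowup_step = -1;

  std::vector<int> spike_buf;
  spike_buf.reserve(256);

  // lookup table for the EIF spike-initiation exponential on x in
  // [-20, 30]; below -20 the term is negligible, above 30 it is clamped
  const int TBL_N = 4096;
  const double tbl_lo = -20.0, tbl_hi = 30.0;
  const double tbl_step = (tbl_hi - tbl_lo) / (TBL_N - 1);
  std::vector<double> exp_tbl(TBL_N);
  for (int i = 0; i < TBL_N; ++i) exp_tbl[i] = std::exp(tbl_lo + i * tbl_step);

  RNGScope scope;
  int bin = -1, cyc = 0;
  double bg = 0.0;
  for (long step = 0; step < n_steps; ++step) {
    int new_bin = (int)(step / steps_per_bin);
    if (new_bin != bin) {
      bin = new_bin;
      cyc = bin_cycle[bin];
      bg = bg_series[bin];
      for (int i = 0; i < n_in; ++i) {
        p_in[i] = in_rates(i, bin) * dt / 1000.0;  // Hz -> prob per step
      }
    }
    spike_buf.clear();
    // input-layer Poisson spikes
    for (int i = 0; i < n_in; ++i) {
      if (p_in[i] > 0.0 && unif_rand() < p_in[i]) spike_buf.push_back(i);
    }
    // EIF membrane update
    for (int j = 0; j < n_eif; ++j) {
      se[j] *= dec_e;
      si[j] *= dec_i;
      if (ref[j] > 0.0) {
        ref[j] -= dt;
        V[j] = Vre[j];
        continue;
      }
      double ex = (V[j] - VT[j]) / DeltaT[j];
      double spike_term;
      if (ex <= tbl_lo) {
        spike_term = 0.0;
      } else {
        if (ex > tbl_hi) ex = tbl_hi;
        double u = (ex - tbl_lo) / tbl_step;
        int i0 = (int)u;
        if (i0 >= TBL_N - 1) i0 = TBL_N - 2;
        double w1 = u - i0;
        spike_term = exp_tbl[i0] * (1.0 - w1) + exp_tbl[i0 + 1] * w1;
      }
      double dV = (-(V[j] - EL[j]) + DeltaT[j] * spike_term) / taum[j]
                  + se[j] + si[j] + mu[j] + bg_weight[j] * bg;
      V[j] += dt * dV;
      if (V[j] < v_floor) V[j] = v_floor;   // reflecting lower bound
      if (!std::isfinite(V[j])) { blowup_step = step; break; }
      if (V[j] >= Vth[j]) {
        spike_buf.push_back(n_in + j);
        V[j] = Vre[j];
        ref[j] = tauref[j];
        ++total_spikes[j];
        if (cyc > 0) counts(cyc - 1, j) += 1;
      } else {
        if (V[j] < v_min) v_min = V[j];
        if (V[j] > v_max) v_max = V[j];
      }
    }
    if (blowup_step >= 0) break;
    // propagate all spikes generated this step
    for (size_t s = 0; s < spike_buf.size(); ++s) {
      int pre = spike_buf[s];
      for (int e = edge_ptr[pre]; e < edge_ptr[pre + 1]; ++e) {
        double w = edge_w[e];
        int tgt = edge_tgt[e];
        if (w >= 0.0) se[tgt] += w; else si[tgt] += w;
      }
    }
  }
  if (blowup_step >= 0) {
    stop("membrane potential became non-finite at step %ld", blowup_step);
  }
  return List::create(
    _["counts"] = counts,
    _["total_spikes"] = IntegerVector(total_spikes.begin(),
                                      total_spikes.end()),
    _["v_min"] = v_min,
    _["v_max"] = v_max,
    _["sim_ms"] = n_steps * dt);
}
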