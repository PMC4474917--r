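#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Fixed-step simulator for a recurrent LIF network with delta synapses,
// lumped Poisson feedforward drive, and optional synaptic plasticity.
//
// Conventions (documented in the package vignette):
//  * W(j, i) is the PSP amplitude (mV) of the synapse from presynaptic j to
//    postsynaptic i; excitatory rows are >= 0, inhibitory rows <= 0.
//  * Exact integration: u <- u * exp(-dt/tau_m) + (sum of PSP jumps).
//  * Recurrent spikes emitted at step t are delivered at step t+1;
//    feedforward Poisson counts drawn at step t act at step t.
//  * At a spike step the voltage entering the plasticity filters and the
//    rectified voltage terms is clamped to u_th; the reset to u_rest is
//    applied after the filter/plasticity update.
//  * Synaptic input is accumulated in ascending presynaptic index order.
//  * Plasticity events (presynaptic trace increments, depression triggers,
//    pre/post events of the rate-homeostatic inhibitory rule) use spike
//    emission times.

// Arguments: pop is 0/1 (excitatory/inhibitory); seg_rates is n_seg x N in
// kHz; snap_after marks segments after which W is snapshotted; record_v_ids
// are 0-based ids whose voltage trace is kept; free_ids are 0-based ids with
// the threshold disabled and E/I input components recorded.
// [[Rcpp::export]]
List sim_core(NumericMatrix W_in, IntegerMatrix mask, IntegerVector pop,
              NumericVector u0, NumericMatrix seg_rates,
              IntegerVector seg_steps, IntegerVector snap_after,
              double dt, double tau_m, double u_th, double u_rest,
              int ref_steps, double J_ffw, Nullable<List> plast_in,
              IntegerVector record_v_ids, IntegerVector free_ids,
              bool record_spikes, bool record_snapshots,
              bool poisson_input) {
  const int N = W_in.nrow();
  const int n_seg = seg_rates.nrow();
  NumericMatrix W = clone(W_in);

  // --- plasticity parameters -------------------------------------------------
  bool plastic = plast_in.isNotNull();
  double a_ltd = 0, a_ltp_exc = 0, a_ltp_inh = 0;
  double th_minus = 0, th_plus = 0, tau_minus = 1, tau_plus = 1, tau_x = 1;
  double u_ref_sq = 1, homeo_ms = 100, wmax_e = 2, wmax_i = 5;
  int rule_ie = 0;     // 0 voltage, 1 vogels, 2 frozen
  int homeo_mode = 0;  // 0 boxcar, 1 exponential
  double eta = 0, alpha = 0;
  if (plastic) {
    List p(plast_in);
    a_ltd = as<double>(p["a_ltd"]);
    a_ltp_exc = as<double>(p["a_ltp_exc"]);
    a_ltp_inh = as<double>(p["a_ltp_inh"]);
    th_minus = as<double>(p["theta_minus"]);
    th_plus = as<double>(p["theta_plus"]);
    tau_minus = as<double>(p["tau_minus"]);
    tau_plus = as<double>(p["tau_plus"]);
    tau_x = as<double>(p["tau_x"]);
    u_ref_sq = as<double>(p["u_ref_sq"]);
    homeo_ms = as<double>(p["homeo_ms"]);
    wmax_e = as<double>(p["wmax_e"]);
    wmax_i = as<double>(p["wmax_i"]);
    rule_ie = as<int>(p["rule_ie"]);
    homeo_mode = as<int>(p["homeo_mode"]);
    eta = as<double>(p["eta"]);
    alpha = as<double>(p["alpha"]);
  }

  // --- adjacency lists for plastic synapses ---------------------------------
  // Voltage rule classes: E->E, E->I always; I->E only if rule_ie == 0.
  std::vector< std::vector<int> > preE_pl(N), preI_pl(N);  // by postsyn column
  std::vector< std::vector<int> > post_pl(N);              // by presyn row
  std::vector< std::vector<int> > vog_post(N), vog_pre(N); // I->E, rate rule
  if (plastic) {
    for (int i = 0; i < N; ++i) {
      for (int j = 0; j < N; ++j) {
        if (!mask(j, i) || j == i) continue;
        if (pop[j] == 0) {  // E->E and E->I, voltage rule
          preE_pl[i].push_back(j);
          post_pl[j].push_back(i);
        } else if (pop[i] == 0) {  // I->E
          if (rule_ie == 0) {
            preI_pl[i].push_back(j);
            post_pl[j].push_back(i);
          } else if (rule_ie == 1) {
            vog_post[j].push_back(i);
            vog_pre[i].push_back(j);
          }
        }
      }
    }
  }

  // --- state -----------------------------------------------------------------
  std::vector<double> u(N), pending(N, 0.0), pending_next(N, 0.0);
  std::vector<double> um(N, 0.0), up(N, 0.0), xbar(N, 0.0), ubb(N, 0.0);
  std::vector<int> refrac(N, 0);
  std::vector<char> is_free(N, 0);
  const int n_free = free_ids.size();
  std::vector<int> free_slot(N, -1);
  for (int k = 0; k < N; ++k) u[k] = u0[k];
  for (int q = 0; q < n_free; ++q) {
    is_free[free_ids[q]] = 1;
    free_slot[free_ids[q]] = q;
  }

  const double decay_m = std::exp(-dt / tau_m);
  const double decay_um = plastic ? std::exp(-dt / tau_minus) : 0;
  const double decay_up = plastic ? std::exp(-dt / tau_plus) : 0;
  const double decay_x = plastic ? std::exp(-dt / tau_x) : 0;
  const double x_inc = plastic ? 1.0 / tau_x : 0;
  const int L = plastic ? std::max(1, (int)std::lround(homeo_ms / dt)) : 1;
  const double decay_bb = plastic ? std::exp(-dt / homeo_ms) : 0;
  std::vector<double> homeo_buf;
  std::vector<double> homeo_sum(N, 0.0);
  int buf_pos = 0;
  if (plastic && homeo_mode == 0) homeo_buf.assign((size_t)N * L, 0.0);

  long total_steps = 0;
  for (int s = 0; s < n_seg; ++s) total_steps += seg_steps[s];

  // --- recording -------------------------------------------------------------
  std::vector<double> spike_t;
  std::vector<int> spike_id;
  if (record_spikes) { spike_t.reserve(1 << 18); spike_id.reserve(1 << 18); }
  IntegerMatrix seg_counts(n_seg, N);
  const int n_rec = record_v_ids.size();
  NumericMatrix v_rec(n_rec > 0 ? total_steps : 0, n_rec);
  NumericMatrix fu(n_free > 0 ? total_steps : 0, n_free);
  NumericMatrix fe(n_free > 0 ? total_steps : 0, n_free);
  NumericMatrix fi(n_free > 0 ? total_steps : 0, n_free);
  std::vector<double> uE(n_free, 0.0), uI(n_free, 0.0);
  std::vector<double> pendE(n_free, 0.0), pendI(n_free, 0.0);
  std::vector<double> pendE_next(n_free, 0.0), pendI_next(n_free, 0.0);
  List snapshots;
  if (record_snapshots) snapshots.push_back(clone(W));

  std::vector<int> spikers; spikers.reserve(N);
  std::vector<double> lambda(N);
  long step = 0;

  // --- main loop -------------------------------------------------------------
  for (int s = 0; s < n_seg; ++s) {
    for (int k = 0; k < N; ++k) lambda[k] = seg_rates(s, k) * dt;
    for (int t = 0; t < seg_steps[s]; ++t, ++step) {
      // feedforward Poisson counts (ascending neuron index) and
      // membrane update by exact integration
      for (int k = 0; k < N; ++k) {
        double ff = 0.0;
        if (lambda[k] > 0) {
          // deterministic mode injects the expected count (mean-drive
          // diagnostic); Poisson mode draws per-step counts
          ff = (poisson_input ? R::rpois(lambda[k]) : lambda[k]) * J_ffw;
        }
        if (refrac[k] > 0) {
          u[k] = u_rest;
          --refrac[k];
        } else {
          u[k] = u[k] * decay_m + pending[k] + ff;
        }
        int q = free_slot[k];
        if (q >= 0) {
          uE[q] = uE[q] * decay_m + pendE[q] + ff;
          uI[q] = uI[q] * decay_m + pendI[q];
        }
      }

      // spike detection (free neurons never cross threshold)
      spikers.clear();
      for (int k = 0; k < N; ++k) {
        if (!is_free[k] && refrac[k] == 0 && u[k] >= u_th) spikers.push_back(k);
      }

      if (plastic) {
        // filters and homeostatic mean (voltage clamped to u_th at spikes)
        for (int k = 0; k < N; ++k) {
          double ue = u[k] > u_th ? u_th : u[k];
          um[k] = ue + (um[k] - ue) * decay_um;
          up[k] = ue + (up[k] - ue) * decay_up;
          if (homeo_mode == 0) {
            size_t idx = (size_t)k * L + buf_pos;
            homeo_sum[k] += ue - homeo_buf[idx];
            homeo_buf[idx] = ue;
            ubb[k] = homeo_sum[k] / L;
          } else {
            ubb[k] = ue + (ubb[k] - ue) * decay_bb;
          }
        }
        if (homeo_mode == 0) buf_pos = (buf_pos + 1) % L;

        // presynaptic traces: decay, then unit-area increments at emission
        for (int k = 0; k < N; ++k) xbar[k] *= decay_x;
        for (size_t n = 0; n < spikers.size(); ++n) xbar[spikers[n]] += x_inc;

        // LTD: one jump per presynaptic spike per plastic synapse
        for (size_t n = 0; n < spikers.size(); ++n) {
          int j = spikers[n];
          const std::vector<int>& tg = post_pl[j];
          bool preE = (pop[j] == 0);
          for (size_t m = 0; m < tg.size(); ++m) {
            int i = tg[m];
            double d = um[i] - th_minus;
            if (d <= 0) continue;
            double amp = a_ltd * (ubb[i] * ubb[i] / u_ref_sq) * d;
            double w = W(j, i);
            if (preE) {
              w -= amp; if (w < 0) w = 0;
            } else {
              w += amp; if (w > 0) w = 0;  // shrink inhibitory magnitude
            }
            W(j, i) = w;
          }
        }

        // LTP: forward-Euler integration of the gated voltage term
        for (int i = 0; i < N; ++i) {
          double ue = u[i] > u_th ? u_th : u[i];
          double g1 = ue - th_plus;
          if (g1 <= 0) continue;
          double g2 = up[i] - th_minus;
          if (g2 <= 0) continue;
          double base = dt * g1 * g2;
          const std::vector<int>& pe = preE_pl[i];
          double* col = &W(0, i);
          double be = a_ltp_exc * base;
          for (size_t m = 0; m < pe.size(); ++m) {
            int j = pe[m];
            double w = col[j] + be * xbar[j];
            col[j] = (w > wmax_e) ? wmax_e : w;
          }
          const std::vector<int>& pi = preI_pl[i];
          double bi = a_ltp_inh * base;
          for (size_t m = 0; m < pi.size(); ++m) {
            int j = pi[m];
            double w = col[j] - bi * xbar[j];  // grow inhibitory magnitude
            col[j] = (w < -wmax_i) ? -wmax_i : w;
          }
        }

        // rate-homeostatic inhibitory rule (I->E), pre/post spike events
        if (rule_ie == 1) {
          for (size_t n = 0; n < spikers.size(); ++n) {
            int k = spikers[n];
            if (pop[k] == 1) {  // presynaptic inhibitory spike
              const std::vector<int>& tg = vog_post[k];
              for (size_t m = 0; m < tg.size(); ++m) {
                int i = tg[m];
                double mag = -W(k, i) + eta * (xbar[i] - alpha);
                if (mag < 0) mag = 0; else if (mag > wmax_i) mag = wmax_i;
                W(k, i) = -mag;
              }
            } else {  // postsynaptic excitatory spike
              const std::vector<int>& pr = vog_pre[k];
              for (size_t m = 0; m < pr.size(); ++m) {
                int j = pr[m];
                double mag = -W(j, k) + eta * xbar[j];
                if (mag < 0) mag = 0; else if (mag > wmax_i) mag = wmax_i;
                W(j, k) = -mag;
              }
            }
          }
        }
      }

      // schedule recurrent PSPs for the next step (ascending presyn index)
      std::fill(pending_next.begin(), pending_next.end(), 0.0);
      std::fill(pendE_next.begin(), pendE_next.end(), 0.0);
      std::fill(pendI_next.begin(), pendI_next.end(), 0.0);
      for (size_t n = 0; n < spikers.size(); ++n) {
        int j = spikers[n];
        for (int i = 0; i < N; ++i) pending_next[i] += W(j, i);
        for (int q = 0; q < n_free; ++q) {
          int i = free_ids[q];
          if (pop[j] == 0) pendE_next[q] += W(j, i);
          else pendI_next[q] += W(j, i);
        }
      }
      pending.swap(pending_next);
      pendE.swap(pendE_next);
      pendI.swap(pendI_next);

      // record spikes, reset, refractoriness
      double t_now = (step + 1) * dt;
      for (size_t n = 0; n < spikers.size(); ++n) {
        int k = spikers[n];
        if (record_spikes) { spike_t.push_back(t_now); spike_id.push_back(k + 1); }
        ++seg_counts(s, k);
        u[k] = u_rest;
        refrac[k] = ref_steps;
      }

      for (int q = 0; q < n_rec; ++q) v_rec(step, q) = u[record_v_ids[q]];
      for (int q = 0; q < n_free; ++q) {
        fu(step, q) = u[free_ids[q]];
        fe(step, q) = uE[q];
        fi(step, q) = uI[q];
      }

      if ((step & 1023) == 0) {
        for (int k = 0; k < N; ++k) {
          if (!std::isfinite(u[k]))
            stop("non-finite membrane potential at t = %f ms (neuron %d): "
                 "parameter blow-up", t_now, k + 1);
        }
      }
    }
    if (snap_after[s] && record_snapshots) snapshots.push_back(clone(W));
  }

  return List::create(
      _["spike_t"] = wrap(spike_t),
      _["spike_id"] = wrap(spike_id),
      _["seg_counts"] = seg_counts,
      _["W_final"] = W,
      _["snapshots"] = snapshots,
      _["v"] = v_rec,
      _["free_u"] = fu,
      _["free_exc"] = fe,
      _["free_inh"] = fi);
}
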