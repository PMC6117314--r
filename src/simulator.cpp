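// Fixed-step engine for leaky integrate-and-fire networks with adaptive
// dendritic terminals. The leak is applied lazily with the exact factor
// exp(-dt/T) (no Euler bias); pulses are binned to their arrival step.
//
// Within a step: deliver all pulses of the bin -> resolve threshold
// crossings (highest voltage first, ties to the lowest terminal index) ->
// convert unconsumed arrivals into sub-threshold stimulation events and run
// the pair-based adaptation against the spike/stimulation histories.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct StimEv { double t; int term; int edge; };
struct SpkEv  { double t; int term; };
struct Arrival { int node; int term; int edge; bool sub; };

struct Engine {
  // topology
  int n_nodes, K, n_edges, mode;
  std::vector<int> e_node, e_term;        // 0-based target node / terminal
  std::vector<double> W;                  // link weights (mutable in link mode)
  std::vector<int> e_dsteps;              // delay in steps (node-sourced edges)
  std::vector<std::vector<int> > out_node; // outgoing edge ids per node

  // parameters
  double dt, T, refractory_ms, f_c;
  double A, tau_adapt, cutoff, noise_amp, j_min, j_max, w_min, w_max;
  int profile;            // 0 exponential, 1 two-level
  bool plastic;
  int ref_steps;

  // state
  std::vector<double> V, J, prev_v, prev_t, t_cross, t_upd, ref_end;
  std::vector<int> prev_stepv, attempted, spiked_step, evok, touched_step;
  std::vector<double> sumW; std::vector<int> cntW;
  std::vector<std::deque<StimEv> > stims;
  std::vector<std::deque<SpkEv> > spks;

  // pulse scheduling
  std::vector<std::vector<int> > ring;
  int ring_size;
  std::vector<std::vector<int> > ref_ring;
  int ref_ring_sz;

  // per-step scratch
  std::vector<Arrival> arrivals;
  std::vector<int> touched;

  // counters / logs
  double count_from, log_from, adapt_from;
  int log_level, adapt_stride;
  long long adapt_ctr = 0, n_fail = 0, n_spk_total = 0;
  std::vector<double> arr_cnt, fire_cnt;     // per edge (double: can be large)
  std::vector<double> node_cnt, term_cnt;    // spike counts in count window
  std::vector<double> ev_t, ev_wj; std::vector<int> ev_node, ev_term, ev_kind;
  std::vector<double> ad_t, ad_delta, ad_before, ad_after, ad_wj;
  std::vector<int> ad_node, ad_term, ad_edge;

  double mean_w(int idx) const { return cntW[idx] ? sumW[idx] / cntW[idx] : 0.0; }

  void touch(int n, double t, int step) {
    if (touched_step[n] == step) return;
    touched_step[n] = step;
    touched.push_back(n);
    double dtl = t - t_upd[n];
    if (dtl > 0) {
      double f = std::exp(-dtl / T);
      for (int k = 0; k < K; ++k) V[n * K + k] *= f;
    }
    t_upd[n] = t;
  }

  bool in_refractory(int n, double t) const {
    return refractory_ms > 0 && t < ref_end[n] - 1e-9;
  }

  void deliver(int e, double t, int step) {
    int n = e_node[e], k = e_term[e], idx = n * K + k;
    touch(n, t, step);
    // the terminal that evoked the ongoing refractory cannot respond to
    // stimulations at all: the pulse is discarded outright
    if (in_refractory(n, t) && k == evok[n]) return;
    if (prev_stepv[idx] != step) {
      prev_v[idx] = V[idx]; prev_t[idx] = t; prev_stepv[idx] = step;
    }
    V[idx] += J[idx] * W[e];
    // a stimulation is sub-threshold only if it leaves the voltage below
    // threshold; pulses that push the terminal to a crossing belong to the
    // resulting spike or response failure (and, during refractory, to the
    // crossing deferred to the end of the window)
    arrivals.push_back({n, k, e, V[idx] < 1.0});
  }

  void force_trigger(int n, double t, int step) {
    touch(n, t, step);
    if (in_refractory(n, t)) return;   // no evoked spike possible now
    int idx = n * K;                   // above-threshold drive on terminal 1
    if (prev_stepv[idx] != step) {
      prev_v[idx] = V[idx]; prev_t[idx] = t; prev_stepv[idx] = step;
    }
    if (V[idx] < 1.0) V[idx] = 1.0;
  }

  void adapt_pair(double t, int n, int k, int e, double dms) {
    double ad = std::fabs(dms);
    if (ad > cutoff || dms == 0.0) return;
    double dlt = (profile == 0) ? A * std::exp(-ad / tau_adapt) : A;
    if (dms < 0) dlt = -dlt;
    double eta = (noise_amp > 0) ? R::runif(-noise_amp, noise_amp) : 0.0;
    double before, after, wj;
    if (mode == 0) {                    // adaptive node: update terminal J
      int idx = n * K + k;
      before = J[idx]; wj = W[e] * before;
      after = before * (1.0 + dlt) + eta;
      if (after < j_min) after = j_min;
      if (after > j_max) after = j_max;
      J[idx] = after;
    } else {                            // adaptive link: update W_m, J fixed
      int idx = n * K + k;
      before = W[e]; wj = before * J[idx];
      after = before * (1.0 + dlt) + eta;
      if (after < w_min) after = w_min;
      if (after > w_max) after = w_max;
      sumW[idx] += after - W[e];
      W[e] = after;
    }
    if (adapt_stride > 0 && t >= adapt_from) {
      if ((adapt_ctr++ % adapt_stride) == 0) {
        ad_t.push_back(t); ad_node.push_back(n); ad_term.push_back(k);
        ad_edge.push_back(e); ad_delta.push_back(dms);
        ad_before.push_back(before); ad_after.push_back(after);
        ad_wj.push_back(wj);
      }
    }
  }

  void resolve(int n, double t, int step) {
    if (in_refractory(n, t)) return;    // threshold checks suspended
    while (true) {
      int best = -1; double bv = -1.0;
      for (int k = 0; k < K; ++k) {
        int idx = n * K + k;
        if (attempted[idx] == step) continue;
        if (V[idx] >= 1.0 && V[idx] > bv) { best = k; bv = V[idx]; }
      }
      if (best < 0) break;
      int idx = n * K + best;
      attempted[idx] = step;
      double dtc = t - t_cross[idx];
      t_cross[idx] = t;
      double P;
      if (f_c <= 0) P = 1.0;
      else { P = dtc * f_c / 1000.0; if (P > 1) P = 1; if (P < 0) P = 0; }
      bool spike = (P >= 1.0) || (unif_rand() < P);
      if (spike) {
        ++n_spk_total;
        if (log_level >= 1 && t >= log_from) {
          ev_t.push_back(t); ev_node.push_back(n); ev_term.push_back(best);
          ev_kind.push_back(0); ev_wj.push_back(J[idx] * mean_w(idx));
        }
        if (t >= count_from) { node_cnt[n] += 1; term_cnt[idx] += 1; }
        V[idx] = 0.0;
        spiked_step[idx] = step;
        if (refractory_ms > 0) {
          ref_end[n] = t + refractory_ms;
          evok[n] = best;
          ref_ring[(step + ref_steps) % ref_ring_sz].push_back(n);
        }
        for (size_t i = 0; i < out_node[n].size(); ++i) {
          int e2 = out_node[n][i];
          ring[(step + e_dsteps[e2]) % ring_size].push_back(e2);
        }
        if (plastic) {
          std::deque<StimEv> &sd = stims[n];
          while (!sd.empty() && t - sd.front().t > cutoff) sd.pop_front();
          for (std::deque<StimEv>::iterator s = sd.begin(); s != sd.end(); ++s) {
            if (mode == 0 && s->term == best) continue;
            adapt_pair(t, n, s->term, s->edge, s->t - t);
          }
          spks[n].push_back({t, best});
          while (!spks[n].empty() && t - spks[n].front().t > cutoff) spks[n].pop_front();
        }
        if (refractory_ms > 0) break;   // node-wide refractory begins
      } else {
        ++n_fail;
        if (log_level >= 2 && t >= log_from) {
          ev_t.push_back(t); ev_node.push_back(n); ev_term.push_back(best);
          ev_kind.push_back(2); ev_wj.push_back(J[idx] * mean_w(idx));
        }
        // response failure: voltage reverts to its pre-pulse value, with
        // the leak continued from the moment that value was stored
        if (prev_stepv[idx] == step) V[idx] = prev_v[idx];
        else V[idx] = prev_v[idx] * std::exp(-(t - prev_t[idx]) / T);
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
List run_network_cpp(List net, List stim, List par, List rec) {
  Engine en;
  en.n_nodes = as<int>(net["n_nodes"]);
  en.K       = as<int>(net["K"]);
  en.mode    = as<int>(net["mode"]);
  IntegerVector src_kind = net["src_kind"], src = net["src"],
                e_node_r = net["node"], e_term_r = net["term"];
  NumericVector w_r = net["W"], delay_r = net["delay_ms"];
  NumericMatrix J_init = net["J_init"];
  int n_inputs = as<int>(net["n_inputs"]);
  en.n_edges = e_node_r.size();

  en.dt            = as<double>(par["dt"]);
  en.T             = as<double>(par["T_ms"]);
  en.refractory_ms = as<double>(par["refractory_ms"]);
  en.f_c           = as<double>(par["f_c"]);
  en.A             = as<double>(par["A"]);
  en.tau_adapt     = as<double>(par["tau_adapt"]);
  en.cutoff        = as<double>(par["cutoff_ms"]);
  en.profile       = as<int>(par["profile"]);
  en.noise_amp     = as<double>(par["noise_amp"]);
  en.j_min         = as<double>(par["j_min"]);
  en.j_max         = as<double>(par["j_max"]);
  en.w_min         = as<double>(par["w_min"]);
  en.w_max         = as<double>(par["w_max"]);
  double duration_ms = as<double>(par["duration_ms"]);
  en.plastic = (en.A != 0.0) || (en.noise_amp > 0.0);

  const int n_steps = (int) std::llround(duration_ms / en.dt);
  en.ref_steps = en.refractory_ms > 0 ? (int) std::llround(en.refractory_ms / en.dt) : 0;
  if (en.ref_steps < 1 && en.refractory_ms > 0) en.ref_steps = 1;

  // --- topology ------------------------------------------------------------
  en.e_node.assign(e_node_r.begin(), e_node_r.end());
  en.e_term.assign(e_term_r.begin(), e_term_r.end());
  en.W.assign(w_r.begin(), w_r.end());
  en.e_dsteps.resize(en.n_edges);
  en.out_node.assign(en.n_nodes, std::vector<int>());
  std::vector<std::vector<int> > out_input(n_inputs);
  int max_d = 1;
  for (int e = 0; e < en.n_edges; ++e) {
    int d = (int) std::llround(delay_r[e] / en.dt);
    if (d < 1) d = 1;
    en.e_dsteps[e] = d;
    if (src_kind[e] == 1) {
      en.out_node[src[e]].push_back(e);
      if (d > max_d) max_d = d;
    } else {
      out_input[src[e]].push_back(e);
    }
  }
  en.ring_size = max_d + 2;
  en.ring.assign(en.ring_size, std::vector<int>());
  en.ref_ring_sz = en.ref_steps + 2;
  en.ref_ring.assign(en.ref_ring_sz, std::vector<int>());

  // --- state ---------------------------------------------------------------
  int NT = en.n_nodes * en.K;
  en.V.assign(NT, 0.0);
  en.J.resize(NT);
  for (int n = 0; n < en.n_nodes; ++n)
    for (int k = 0; k < en.K; ++k) en.J[n * en.K + k] = J_init(n, k);
  en.prev_v.assign(NT, 0.0); en.prev_t.assign(NT, 0.0);
  en.prev_stepv.assign(NT, -1);
  en.t_cross.assign(NT, -1e300);
  en.attempted.assign(NT, -1); en.spiked_step.assign(NT, -1);
  en.t_upd.assign(en.n_nodes, 0.0);
  en.ref_end.assign(en.n_nodes, -1e300);
  en.evok.assign(en.n_nodes, -1);
  en.touched_step.assign(en.n_nodes, -1);
  en.sumW.assign(NT, 0.0); en.cntW.assign(NT, 0);
  for (int e = 0; e < en.n_edges; ++e) {
    int idx = en.e_node[e] * en.K + en.e_term[e];
    en.sumW[idx] += en.W[e]; en.cntW[idx] += 1;
  }
  en.stims.assign(en.n_nodes, std::deque<StimEv>());
  en.spks.assign(en.n_nodes, std::deque<SpkEv>());
  en.arr_cnt.assign(en.n_edges, 0.0); en.fire_cnt.assign(en.n_edges, 0.0);
  en.node_cnt.assign(en.n_nodes, 0.0); en.term_cnt.assign(NT, 0.0);

  // --- external input pulses, pre-binned and sorted ------------------------
  List input_spikes = stim["input_spikes"];
  std::vector<std::pair<int, int> > ext;    // (arrival step, edge)
  for (int i = 0; i < n_inputs; ++i) {
    NumericVector ts = input_spikes[i];
    for (int s = 0; s < ts.size(); ++s) {
      for (size_t q = 0; q < out_input[i].size(); ++q) {
        int e = out_input[i][q];
        long long st = std::llround((ts[s] + delay_r[e]) / en.dt);
        if (st >= 0 && st <= n_steps) ext.push_back(std::make_pair((int) st, e));
      }
    }
  }
  std::sort(ext.begin(), ext.end());
  size_t ext_ptr = 0;

  NumericVector trg_t = stim["trigger_times"];
  IntegerVector trg_n = stim["trigger_nodes"];
  std::vector<std::pair<int, int> > trg;
  for (int i = 0; i < trg_t.size(); ++i) {
    long long st = std::llround(trg_t[i] / en.dt);
    if (st >= 0 && st <= n_steps) trg.push_back(std::make_pair((int) st, trg_n[i]));
  }
  std::sort(trg.begin(), trg.end());
  size_t trg_ptr = 0;

  // --- recording setup -----------------------------------------------------
  en.count_from   = as<double>(rec["count_from_ms"]);
  en.log_level    = as<int>(rec["log_level"]);
  en.log_from     = as<double>(rec["log_from_ms"]);
  en.adapt_stride = as<int>(rec["adapt_log_stride"]);
  en.adapt_from   = as<double>(rec["adapt_log_from_ms"]);
  double recJ_every = as<double>(rec["record_J_every_ms"]);
  IntegerVector rec_nodes = rec["record_nodes"];
  double sampW_every = as<double>(rec["sample_weights_every_ms"]);
  double sampW_from  = as<double>(rec["sample_weights_from_ms"]);

  int recJ_steps = recJ_every > 0 ? (int) std::llround(recJ_every / en.dt) : 0;
  if (recJ_steps < 1 && recJ_every > 0) recJ_steps = 1;
  int n_recJ = recJ_steps > 0 ? n_steps / recJ_steps + 1 : 0;
  NumericMatrix J_traces(n_recJ, recJ_steps > 0 ? rec_nodes.size() * en.K : 0);
  NumericVector J_times(n_recJ);
  int recJ_row = 0;

  int sampW_steps = sampW_every > 0 ? (int) std::llround(sampW_every / en.dt) : 0;
  if (sampW_steps < 1 && sampW_every > 0) sampW_steps = 1;
  int n_sampW = 0;
  if (sampW_steps > 0)
    for (int s = 0; s <= n_steps; s += sampW_steps)
      if (s * en.dt >= sampW_from) ++n_sampW;
  NumericMatrix wj_samples(n_sampW, sampW_steps > 0 ? en.n_edges : 0);
  NumericVector wj_times(n_sampW);
  int sampW_row = 0;

  // --- main loop -----------------------------------------------------------
  for (int step = 0; step <= n_steps; ++step) {
    double t = step * en.dt;

    std::vector<int> &slot = en.ring[step % en.ring_size];
    for (size_t i = 0; i < slot.size(); ++i) en.deliver(slot[i], t, step);
    slot.clear();
    while (ext_ptr < ext.size() && ext[ext_ptr].first == step)
      en.deliver(ext[ext_ptr++].second, t, step);
    while (trg_ptr < trg.size() && trg[trg_ptr].first == step)
      en.force_trigger(trg[trg_ptr++].second, t, step);
    std::vector<int> &rs = en.ref_ring[step % en.ref_ring_sz];
    for (size_t i = 0; i < rs.size(); ++i) en.touch(rs[i], t, step);
    rs.clear();

    if (!en.touched.empty()) {
      std::sort(en.touched.begin(), en.touched.end());
      for (size_t i = 0; i < en.touched.size(); ++i) en.resolve(en.touched[i], t, step);

      // unconsumed arrivals become sub-threshold stimulation events
      for (size_t i = 0; i < en.arrivals.size(); ++i) {
        const Arrival &a = en.arrivals[i];
        int idx = a.node * en.K + a.term;
        bool consumed = (en.spiked_step[idx] == step);
        if (t >= en.count_from) {
          en.arr_cnt[a.edge] += 1;
          if (consumed) en.fire_cnt[a.edge] += 1;
        }
        if (consumed) continue;
        // arrivals tied to a crossing (a spike or a response failure, or a
        // crossing deferred past the refractory window) are not part of the
        // sub-threshold stimulation stream and never pair
        if (en.attempted[idx] == step || !a.sub) continue;
        if (en.log_level >= 3 && t >= en.log_from) {
          en.ev_t.push_back(t); en.ev_node.push_back(a.node);
          en.ev_term.push_back(a.term); en.ev_kind.push_back(1);
          en.ev_wj.push_back(en.J[idx] * en.W[a.edge]);
        }
        if (en.plastic) {
          std::deque<SpkEv> &pd = en.spks[a.node];
          while (!pd.empty() && t - pd.front().t > en.cutoff) pd.pop_front();
          for (std::deque<SpkEv>::iterator p = pd.begin(); p != pd.end(); ++p) {
            if (en.mode == 0 && p->term == a.term) continue;
            en.adapt_pair(t, a.node, a.term, a.edge, t - p->t);
          }
          std::deque<StimEv> &sd = en.stims[a.node];
          sd.push_back({t, a.term, a.edge});
          while (!sd.empty() && t - sd.front().t > en.cutoff) sd.pop_front();
        }
      }
      en.arrivals.clear();
      en.touched.clear();
    }

    if (recJ_steps > 0 && step % recJ_steps == 0) {
      J_times[recJ_row] = t;
      for (int i = 0; i < rec_nodes.size(); ++i)
        for (int k = 0; k < en.K; ++k)
          J_traces(recJ_row, i * en.K + k) = en.J[rec_nodes[i] * en.K + k];
      ++recJ_row;
    }
    if (sampW_steps > 0 && step % sampW_steps == 0 && t >= sampW_from) {
      wj_times[sampW_row] = t;
      for (int e = 0; e < en.n_edges; ++e)
        wj_samples(sampW_row, e) = en.W[e] * en.J[en.e_node[e] * en.K + en.e_term[e]];
      ++sampW_row;
    }
    if ((step & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // settle the lazy leak: decay every terminal to the end of the run
  double t_end = n_steps * en.dt;
  NumericMatrix J_final(en.n_nodes, en.K), V_final(en.n_nodes, en.K);
  for (int n = 0; n < en.n_nodes; ++n) {
    double f = std::exp(-(t_end - en.t_upd[n]) / en.T);
    for (int k = 0; k < en.K; ++k) {
      J_final(n, k) = en.J[n * en.K + k];
      V_final(n, k) = en.V[n * en.K + k] * f;
    }
  }

  return List::create(
    _["events"] = List::create(
      _["time_ms"] = wrap(en.ev_t), _["node"] = wrap(en.ev_node),
      _["terminal"] = wrap(en.ev_term), _["kind"] = wrap(en.ev_kind),
      _["wj"] = wrap(en.ev_wj)),
    _["adapt_log"] = List::create(
      _["time_ms"] = wrap(en.ad_t), _["node"] = wrap(en.ad_node),
      _["terminal"] = wrap(en.ad_term), _["edge"] = wrap(en.ad_edge),
      _["delta_ms"] = wrap(en.ad_delta), _["j_before"] = wrap(en.ad_before),
      _["j_after"] = wrap(en.ad_after), _["wj"] = wrap(en.ad_wj)),
    _["J_times_ms"] = J_times, _["J_traces"] = J_traces,
    _["wj_times_ms"] = wj_times, _["wj_samples"] = wj_samples,
    _["J_final"] = J_final, _["V_final"] = V_final,
    _["W_final"] = wrap(en.W),
    _["edge_arrivals"] = wrap(en.arr_cnt), _["edge_firing"] = wrap(en.fire_cnt),
    _["node_spikes"] = wrap(en.node_cnt), _["terminal_spikes"] = wrap(en.term_cnt),
    _["n_failures"] = (double) en.n_fail,
    _["n_spikes"] = (double) en.n_spk_total);
}
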