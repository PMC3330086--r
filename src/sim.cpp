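// Event-driven simulation of a delayed pulse-coupled LIF network in phase
// representation.  The core is fully deterministic given its inputs: all
// randomness (initial phases, in-transit spikes, stimulus target sets) is
// drawn in R and passed in.
//
// Conventions (must stay in sync with the R-level phase_functions):
//   U(phi)    = I/g + (Vr - I/g) exp(-g phi)
//   U_inv(V)  = log((I - g Vr)/(I - g V)) / g,  defined for V < I/g
//   threshold = fire iff V + lambda >= V_theta (the arriving input counts)
//   reset     = potential set to V_reset exactly, overshoot discarded
// Events closer than 1e-9*tau are treated as simultaneous; a wave is the set
// of all spikes arriving at one such instant, whose excitatory strengths are
// summed, passed through the dendritic modulation, and combined with the
// linearly summed inhibition.  All wave targets are updated synchronously
// from their pre-delivery phases.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

struct Wave {
  double t;
  std::vector<int> senders;  // 0-based
};

struct WaveCmp {
  const std::vector<Wave>* waves;
  bool operator()(int a, int b) const { return (*waves)[a].t > (*waves)[b].t; }
};

struct HeapEntry {
  double t;
  int id;
};
struct HeapCmp {
  bool operator()(const HeapEntry& a, const HeapEntry& b) const {
    return a.t > b.t;
  }
};

}  // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int N,
              IntegerVector out_ptr,     // length N+1, 0-based CSR
              IntegerVector out_tgt,     // 0-based targets
              NumericVector out_w,       // strengths
              NumericVector phases0,     // length N, < phi_theta
              NumericVector transit_dt,  // arrival times relative to t = 0
              IntegerVector transit_sender,  // 0-based
              NumericVector stim_times,
              List stim_sets,            // 0-based integer vectors
              double duration,
              double gamma_, double I_ext, double V_theta, double V_reset,
              double tau,
              double theta_b, double theta_s, double s_sat, bool mod_linear,
              double guard_rate, double max_spikes) {
  // guard_rate: abort if more than guard_rate spikes arrive per unit time
  // network-wide (0 disables); max_spikes: hard cap on recorded spikes.
  const double Vinf = I_ext / gamma_;
  const double Tfree = std::log((I_ext - gamma_ * V_reset) /
                                (I_ext - gamma_ * V_theta)) / gamma_;
  const double phi_theta = Tfree;
  const double tol = 1e-9 * tau;
  const double INF = std::numeric_limits<double>::infinity();

  auto U = [&](double phi) {
    return Vinf + (V_reset - Vinf) * std::exp(-gamma_ * phi);
  };
  auto U_inv = [&](double V) {
    return std::log((I_ext - gamma_ * V_reset) / (I_ext - gamma_ * V)) /
           gamma_;
  };
  auto sigma = [&](double x) {
    if (mod_linear || x <= theta_b) return x;
    if (x >= theta_s) return s_sat;
    return theta_b + (s_sat - theta_b) * (x - theta_b) / (theta_s - theta_b);
  };

  // absolute time of next free threshold crossing
  std::vector<double> nextfree(N);
  for (int i = 0; i < N; ++i) nextfree[i] = phi_theta - phases0[i];

  // lazy min-heap over free crossings (entries validated against nextfree)
  std::vector<HeapEntry> heap;
  heap.reserve(4 * N);
  HeapCmp hcmp;
  auto heap_push = [&](int id) {
    heap.push_back({nextfree[id], id});
    std::push_heap(heap.begin(), heap.end(), hcmp);
    if ((int)heap.size() > 8 * N + 1024) {  // compact stale entries
      heap.clear();
      for (int i = 0; i < N; ++i) heap.push_back({nextfree[i], i});
      std::make_heap(heap.begin(), heap.end(), hcmp);
    }
  };
  for (int i = 0; i < N; ++i) heap.push_back({nextfree[i], i});
  std::make_heap(heap.begin(), heap.end(), hcmp);
  auto heap_peek = [&]() {
    while (!heap.empty() && heap.front().t != nextfree[heap.front().id]) {
      std::pop_heap(heap.begin(), heap.end(), hcmp);
      heap.pop_back();
    }
    return heap.empty() ? INF : heap.front().t;
  };

  // in-transit waves
  std::vector<Wave> waves;
  WaveCmp wcmp{&waves};
  std::priority_queue<int, std::vector<int>, WaveCmp> arrivals(wcmp);
  {
    std::map<double, std::vector<int> > grp;
    for (int k = 0; k < transit_dt.size(); ++k)
      grp[transit_dt[k]].push_back(transit_sender[k]);
    for (auto& kv : grp) {
      waves.push_back({kv.first, kv.second});
      arrivals.push((int)waves.size() - 1);
    }
  }

  // outputs
  std::vector<double> sp_t;
  std::vector<int> sp_id, sp_tag;
  bool aborted = false;
  std::string abort_reason = "";
  size_t guard_lo = 0;  // sliding-window pointer for the rate guard

  // per-instant scratch, epoch-stamped to avoid clearing
  std::vector<double> excsum(N, 0.0), inhsum(N, 0.0);
  std::vector<long> touch_ep(N, -1), fired_ep(N, -1), thr_ep(N, -1);
  long epoch = 0;
  std::vector<int> touched;
  touched.reserve(N);

  int stim_ptr = 0;
  const int n_stim = stim_times.size();
  int n_clamped = 0;

  auto record = [&](double t, int id, int tag) {
    sp_t.push_back(t);
    sp_id.push_back(id);
    sp_tag.push_back(tag);
  };

  std::vector<std::pair<double, int> > emitters;  // (spike time, id)

  while (true) {
    double t_free = heap_peek();
    double t_arr = arrivals.empty() ? INF : waves[arrivals.top()].t;
    double t_stim = stim_ptr < n_stim ? stim_times[stim_ptr] : INF;
    double t_ev = std::min(t_free, std::min(t_arr, t_stim));
    if (t_ev > duration) break;
    ++epoch;
    emitters.clear();
    touched.clear();

    // -- gather all spikes arriving within the simultaneity tolerance
    bool has_wave = false;
    std::vector<int> wave_senders;
    while (!arrivals.empty() && waves[arrivals.top()].t <= t_ev + tol) {
      int wi = arrivals.top();
      arrivals.pop();
      has_wave = true;
      wave_senders.insert(wave_senders.end(), waves[wi].senders.begin(),
                          waves[wi].senders.end());
      std::vector<int>().swap(waves[wi].senders);
    }

    // -- free threshold crossings at this instant (may be claimed by a wave)
    std::vector<std::pair<double, int> > crossers;
    while (!heap.empty()) {
      HeapEntry e = heap.front();
      if (e.t != nextfree[e.id]) {  // stale
        std::pop_heap(heap.begin(), heap.end(), hcmp);
        heap.pop_back();
        continue;
      }
      if (e.t > t_ev + tol) break;
      std::pop_heap(heap.begin(), heap.end(), hcmp);
      heap.pop_back();
      crossers.push_back({e.t, e.id});
      thr_ep[e.id] = epoch;
    }

    // -- deliver the wave synchronously from pre-delivery phases
    if (has_wave) {
      for (int s : wave_senders) {
        for (int k = out_ptr[s]; k < out_ptr[s + 1]; ++k) {
          int i = out_tgt[k];
          if (touch_ep[i] != epoch) {
            touch_ep[i] = epoch;
            excsum[i] = 0.0;
            inhsum[i] = 0.0;
            touched.push_back(i);
          }
          double w = out_w[k];
          if (w > 0) excsum[i] += w; else inhsum[i] += w;
        }
      }
      for (int i : touched) {
        double lam = sigma(excsum[i]) + inhsum[i];
        double phi = phi_theta - (nextfree[i] - t_ev);
        double V = U(phi);
        if (V + lam >= V_theta) {
          nextfree[i] = t_ev + Tfree;
          heap_push(i);
          fired_ep[i] = epoch;
          record(t_ev, i, 0);
          emitters.push_back({t_ev, i});
        } else {
          double Vn = V + lam;
          if (Vn <= -Vinf) { Vn = -Vinf + 1e-12; ++n_clamped; }
          nextfree[i] = t_ev + (phi_theta - U_inv(Vn));
          heap_push(i);
        }
      }
    }

    // -- free crossers not touched by a coincident wave fire on their own,
    //    stamped at their exact crossing time
    for (auto& c : crossers) {
      int i = c.second;
      if (touch_ep[i] == epoch) continue;  // wave decided for this neuron
      nextfree[i] = c.first + Tfree;
      heap_push(i);
      fired_ep[i] = epoch;
      record(c.first, i, 0);
      emitters.push_back({c.first, i});
    }

    // -- external supra-threshold stimulation forces immediate spiking
    while (stim_ptr < n_stim && stim_times[stim_ptr] <= t_ev + tol) {
      double ts = stim_times[stim_ptr];
      IntegerVector set = stim_sets[stim_ptr];
      for (int k = 0; k < set.size(); ++k) {
        int i = set[k];
        if (fired_ep[i] == epoch) {  // already spiked this instant: retag
          for (size_t q = sp_t.size(); q-- > 0 && sp_t[q] >= t_ev - tol;)
            if (sp_id[q] == i) { sp_tag[q] = 2; break; }
          continue;
        }
        nextfree[i] = ts + Tfree;
        heap_push(i);
        fired_ep[i] = epoch;
        record(ts, i, 2);
        emitters.push_back({ts, i});
      }
      ++stim_ptr;
    }

    // -- everything emitted at this instant travels together: enqueue the
    //    outgoing wave(s), one per exact spike time (sub-tolerance spread
    //    re-merges on arrival)
    if (!emitters.empty()) {
      std::map<double, std::vector<int> > grp;
      for (auto& e : emitters) grp[e.first].push_back(e.second);
      for (auto& kv : grp) {
        waves.push_back({kv.first + tau, kv.second});
        arrivals.push((int)waves.size() - 1);
      }
    }

    // -- guards
    if (max_spikes > 0 && (double)sp_t.size() > max_spikes) {
      aborted = true;
      abort_reason = "max_spikes exceeded";
      break;
    }
    if (guard_rate > 0) {
      while (guard_lo < sp_t.size() && sp_t[guard_lo] < t_ev - 1.0)
        ++guard_lo;
      if ((double)(sp_t.size() - guard_lo) > guard_rate) {
        aborted = true;
        abort_reason = "spike-rate guard tripped (unstable background)";
        break;
      }
    }
  }

  double t_end = aborted ? (sp_t.empty() ? 0.0 : sp_t.back()) : duration;

  // final phases and still-in-transit spikes (times relative to t_end)
  NumericVector phases_end(N);
  for (int i = 0; i < N; ++i) phases_end[i] = phi_theta - (nextfree[i] - t_end);
  std::vector<double> rem_dt;
  std::vector<int> rem_sender;
  while (!arrivals.empty()) {
    int wi = arrivals.top();
    arrivals.pop();
    for (int s : waves[wi].senders) {
      rem_dt.push_back(waves[wi].t - t_end);
      rem_sender.push_back(s);
    }
  }

  return List::create(
      _["times"] = wrap(sp_t), _["ids"] = wrap(sp_id),
      _["tags"] = wrap(sp_tag), _["phases_end"] = phases_end,
      _["transit_dt"] = wrap(rem_dt), _["transit_sender"] = wrap(rem_sender),
      _["aborted"] = aborted, _["abort_reason"] = abort_reason,
      _["t_end"] = t_end, _["n_clamped"] = n_clamped);
}
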