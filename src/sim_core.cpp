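// Discrete-event core for the tandem ED -> IU system.
//
// ED: c1 beds, preemptive-resume priority across K classes (class 1
// preempts; victim = lowest priority, latest service start; preempted work
// resumes). On ED completion a patient needs the IU w.p. x; if the IU
// (c2 beds, no buffer) is full the patient "boards", holding the ED bed
// until an IU departure. Boarders are served FCFS at IU departures and are
// not preemptible. Direct IU arrivals are lost when the IU is full.
//
// All randomness comes from R's RNG stream, so set.seed() in R makes runs
// bitwise reproducible.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Event {
  double t;
  int type;       // 0 ED arrival (id=class), 1 direct IU arrival,
                  // 2 ED completion (id=patient), 3 IU departure
  int id;
  int epoch;      // invalidation counter for completions
  long seq;       // FIFO tie-break at equal times
};
struct EventCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;
  }
};

struct Patient {
  int cls;
  double t_arr;
  double rem;        // remaining service requirement
  double seg_start;  // start of the current service segment
  double t_first;    // first time a bed was obtained (-1 = never)
  int epoch;
  bool in_service;
};

// kind 0: triangular(a, m, b); kind 1: exponential(rate)
double draw_time(const double* par) {
  if (par[0] < 0.5) {
    double a = par[1], m = par[2], b = par[3];
    if (b <= a) return a;
    double u = R::runif(0.0, 1.0);
    double fc = (m - a) / (b - a);
    if (u < fc) return a + std::sqrt(u * (b - a) * (m - a));
    return b - std::sqrt((1.0 - u) * (b - a) * (b - m));
  }
  return R::exp_rand() / par[1];
}

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector lambda, NumericMatrix svc, NumericVector iu_dist,
              int c1, int c2, double x, double lambda_direct,
              double horizon, double warmup) {
  const int K = lambda.size();
  std::priority_queue<Event, std::vector<Event>, EventCmp> ev;
  long seq = 0;
  std::vector<Patient> pats;
  std::vector<std::deque<int>> qs(K);
  std::deque<int> boarders;
  std::vector<int> serving;           // patient ids currently in service
  int free_ed = c1, iu_busy = 0;

  // statistics
  std::vector<double> sum_delay(K, 0.0), sum_sys(K, 0.0), areaL(K, 0.0);
  std::vector<int> n_delay(K, 0), n_sys(K, 0), n_arr(K, 0), n_in(K, 0);
  double area_ed = 0.0, area_iu = 0.0;
  long tr_attempt = 0, tr_blocked = 0, di_attempt = 0, di_lost = 0;
  long preemptions = 0;
  double last_t = 0.0;

  auto push = [&](double t, int type, int id, int epoch) {
    ev.push(Event{t, type, id, epoch, seq++});
  };

  // seed arrival streams
  for (int k = 0; k < K; ++k)
    if (lambda[k] > 0) push(R::exp_rand() / lambda[k], 0, k, 0);
  if (lambda_direct > 0) push(R::exp_rand() / lambda_direct, 1, 0, 0);

  auto advance_stats = [&](double t) {
    double lo = std::max(last_t, warmup), hi = std::min(t, horizon);
    if (hi > lo) {
      double dt = hi - lo;
      for (int k = 0; k < K; ++k) areaL[k] += dt * n_in[k];
      area_ed += dt * (c1 - free_ed);
      area_iu += dt * iu_busy;
    }
    last_t = t;
  };

  auto draw_svc = [&](int k) {
    double par[4] = {svc(k, 0), svc(k, 1), svc(k, 2), svc(k, 3)};
    return draw_time(par);
  };
  auto draw_los = [&]() {
    double par[4] = {iu_dist[0], iu_dist[1], iu_dist[2], iu_dist[3]};
    return draw_time(par);
  };

  auto start_service = [&](int id, double t) {
    Patient& p = pats[id];
    p.in_service = true;
    p.seg_start = t;
    if (p.t_first < 0) {
      p.t_first = t;
      if (p.t_arr >= warmup && t <= horizon) {
        sum_delay[p.cls] += t - p.t_arr;
        n_delay[p.cls] += 1;
      }
    }
    serving.push_back(id);
    --free_ed;
    push(t + p.rem, 2, id, p.epoch);
  };

  auto serve_next = [&](double t) {
    while (free_ed > 0) {
      int pick = -1;
      for (int k = 0; k < K; ++k)
        if (!qs[k].empty()) { pick = k; break; }
      if (pick < 0) break;
      int id = qs[pick].front();
      qs[pick].pop_front();
      start_service(id, t);
    }
  };

  auto remove_serving = [&](int id) {
    for (size_t i = 0; i < serving.size(); ++i)
      if (serving[i] == id) { serving[i] = serving.back(); serving.pop_back(); return; }
  };

  auto release_bed = [&](int id, double t) {   // patient leaves its ED bed
    Patient& p = pats[id];
    if (p.t_arr >= warmup && t <= horizon) {
      sum_sys[p.cls] += t - p.t_arr;
      n_sys[p.cls] += 1;
    }
    n_in[p.cls] -= 1;
    ++free_ed;
  };

  auto admit_iu = [&](double t) {
    ++iu_busy;
    push(t + draw_los(), 3, 0, 0);
  };

  while (!ev.empty()) {
    Event e = ev.top(); ev.pop();
    if (e.type == 2 && pats[e.id].epoch != e.epoch) continue;  // stale
    if (e.t > horizon) { advance_stats(horizon); break; }
    advance_stats(e.t);

    switch (e.type) {
    case 0: {                                   // ED arrival, class e.id
      int k = e.id;
      push(e.t + R::exp_rand() / lambda[k], 0, k, 0);
      Patient p{k, e.t, draw_svc(k), e.t, -1.0, 0, false};
      pats.push_back(p);
      int id = (int)pats.size() - 1;
      n_in[k] += 1;
      if (e.t >= warmup) n_arr[k] += 1;
      if (free_ed == 0) {
        // preemption: weakest in-service patient, latest segment start
        int victim = -1;
        for (int sid : serving) {
          const Patient& s = pats[sid];
          if (s.cls > k &&
              (victim < 0 || s.cls > pats[victim].cls ||
               (s.cls == pats[victim].cls &&
                s.seg_start > pats[victim].seg_start)))
            victim = sid;
        }
        if (victim >= 0) {
          Patient& v = pats[victim];
          v.rem -= (e.t - v.seg_start);
          if (v.rem < 0) v.rem = 0;
          v.epoch += 1;
          v.in_service = false;
          remove_serving(victim);
          ++free_ed;
          qs[v.cls].push_front(victim);        // resume semantics
          if (e.t >= warmup) ++preemptions;
        }
      }
      qs[k].push_back(id);
      serve_next(e.t);
      break;
    }
    case 1: {                                   // direct IU arrival
      push(e.t + R::exp_rand() / lambda_direct, 1, 0, 0);
      if (e.t >= warmup) ++di_attempt;
      if (iu_busy < c2) admit_iu(e.t);
      else if (e.t >= warmup) ++di_lost;
      break;
    }
    case 2: {                                   // ED service completion
      int id = e.id;
      Patient& p = pats[id];
      p.in_service = false;
      remove_serving(id);
      bool needs_iu = (x > 0.0) && (R::runif(0.0, 1.0) < x);
      if (!needs_iu) {
        release_bed(id, e.t);
        serve_next(e.t);
      } else {
        if (e.t >= warmup) ++tr_attempt;
        if (iu_busy < c2) {
          admit_iu(e.t);
          release_bed(id, e.t);
          serve_next(e.t);
        } else {
          if (e.t >= warmup) ++tr_blocked;
          boarders.push_back(id);               // keeps its ED bed
        }
      }
      break;
    }
    case 3: {                                   // IU departure
      --iu_busy;
      if (!boarders.empty()) {
        int id = boarders.front(); boarders.pop_front();
        admit_iu(e.t);
        release_bed(id, e.t);
        serve_next(e.t);
      }
      break;
    }
    }
  }
  if (last_t < horizon) advance_stats(horizon);

  double span = horizon - warmup;
  return List::create(
    _["n_delay"] = wrap(n_delay), _["sum_delay"] = wrap(sum_delay),
    _["n_sys"] = wrap(n_sys), _["sum_sys"] = wrap(sum_sys),
    _["n_arrivals"] = wrap(n_arr), _["area_L"] = wrap(areaL),
    _["area_ed"] = area_ed, _["area_iu"] = area_iu,
    _["transfer_attempts"] = (double)tr_attempt,
    _["transfer_blocked"] = (double)tr_blocked,
    _["direct_attempts"] = (double)di_attempt,
    _["direct_lost"] = (double)di_lost,
    _["preemptions"] = (double)preemptions,
    _["span"] = span);
}
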