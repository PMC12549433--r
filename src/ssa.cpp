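#include <Rcpp.h>
using namespace Rcpp;

// Table-driven Gillespie simulation on an enumerated lattice.
//
// rates:   n_states x n_jumps matrix of transition rates (0 = forbidden)
// target:  n_states x n_jumps matrix of 1-based destination indices
//          (ignored where the rate is 0)
// x0:      1-based starting state index
// origin:  1-based index of the absorbing origin state
// t_max:   simulation horizon
// t0:      occupation accumulation starts at t0 (when occupy = true)
// occupy:  accumulate time spent per state on (t0, min(extinction, t_max))
// record:  store the full event sequence (times + state indices)
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List ssa_run(NumericMatrix rates, IntegerMatrix target,
             int x0, int origin, double t_max, double t0,
             bool occupy, bool record) {
  const int n = rates.nrow();
  const int m = rates.ncol();
  std::vector<double> total(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += rates(i, j);
    total[i] = s;
  }
  std::vector<double> occ;
  if (occupy) occ.assign(n, 0.0);
  std::vector<double> ev_t;
  std::vector<int> ev_s;
  int state = x0 - 1;
  double t = 0.0;
  bool extinct = false;
  double t_ext = NA_REAL;
  if (record) { ev_t.push_back(0.0); ev_s.push_back(state + 1); }
  while (true) {
    if (state == origin - 1 || total[state] <= 0.0) {
      extinct = true;
      t_ext = t;
      break;
    }
    double dt = ::Rf_rexp(1.0) / total[state];
    double t_next = t + dt;
    if (occupy) {
      double a = std::max(t, t0);
      double b = std::min(t_next, t_max);
      if (b > a) occ[state] += b - a;
    }
    if (t_next >= t_max) { t = t_max; break; }
    double u = ::unif_rand() * total[state];
    double acc = 0.0;
    int j = 0;
    for (; j < m - 1; ++j) {
      acc += rates(state, j);
      if (u <= acc) break;
    }
    state = target(state, j) - 1;
    t = t_next;
    if (record) { ev_t.push_back(t); ev_s.push_back(state + 1); }
    if ((ev_t.size() & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(
    _["extinct"] = extinct,
    _["time"] = t_ext,
    _["t_end"] = t);
  if (occupy) out["occupation"] = NumericVector(occ.begin(), occ.end());
  if (record) {
    out["event_times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_states"] = IntegerVector(ev_s.begin(), ev_s.end());
  }
  return out;
}
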