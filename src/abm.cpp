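#include <Rcpp.h>
#include <queue>
#include <vector>
#include <utility>
using namespace Rcpp;

typedef std::pair<double, int> Event; // (division time, cell index)

// First-reaction event loop of the agent-based model. Each cell carries a
// barcode, a division rate and a scheduled next-division time; events are
// processed in time order from a binary heap. At division the parent is
// replaced by two children; each child draws its own rate
// r_c = r_p * max(Y, 0), Y ~ Normal(1, sigma_m), and its own exponential
// waiting time t = -ln(R)/r_c. Children with rate 0 are never scheduled.
// No stale events exist: a parent's pending event is consumed by its
// division. Runs until the population reaches n_crit cells; if the heap
// empties first (every remaining rate is 0) the run is flagged as stalled.
// [[Rcpp::export]]
List cpp_abm_grow(IntegerVector barcode, NumericVector rate,
                  NumericVector tnext, double now, double n_crit,
                  double sigma_m) {
  int n0 = barcode.size();
  int target = (int)n_crit;
  int cap = std::max(n0, target) + 1;
  std::vector<int> bc(cap);
  std::vector<double> r(cap), tn(cap);
  for (int i = 0; i < n0; ++i) {
    bc[i] = barcode[i];
    r[i] = rate[i];
    tn[i] = tnext[i];
  }

  std::priority_queue<Event, std::vector<Event>, std::greater<Event> > heap;
  for (int i = 0; i < n0; ++i)
    if (r[i] > 0.0 && R_FINITE(tn[i])) heap.push(Event(tn[i], i));

  int n = n0;
  double t = now;
  bool stalled = false;

  while (n < target) {
    if (heap.empty()) { stalled = true; break; }
    Event ev = heap.top();
    heap.pop();
    t = ev.first;
    int p = ev.second;
    double rp = r[p];
    // two children: one reuses the parent's slot, one appends
    int idx[2] = {p, n};
    for (int c = 0; c < 2; ++c) {
      int i = idx[c];
      double y = sigma_m > 0.0 ? R::rnorm(1.0, sigma_m) : 1.0;
      double rc = rp * (y > 0.0 ? y : 0.0);
      bc[i] = bc[p];
      r[i] = rc;
      if (rc > 0.0) {
        tn[i] = t - std::log(unif_rand()) / rc;
        heap.push(Event(tn[i], i));
      } else {
        tn[i] = R_PosInf;
      }
    }
    ++n;
  }

  return List::create(
      _["barcode"] = IntegerVector(bc.begin(), bc.begin() + n),
      _["rate"] = NumericVector(r.begin(), r.begin() + n),
      _["tnext"] = NumericVector(tn.begin(), tn.begin() + n),
      _["now"] = t, _["elapsed"] = t - now, _["stalled"] = stalled);
}
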