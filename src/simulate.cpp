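#include <Rcpp.h>
using namespace Rcpp;

// Turn-by-turn simulation of the knowledge process. One turn is the same
// exclusive mixture as the transition matrix: with probability q_C / N the
// good arm relocates and every agent forgets it; otherwise one agent is
// chosen uniformly, and if uninformed he attempts social learning with
// probability r_n (success probability q_O, possible only while someone
// else is informed) or individual learning (success probability q_I).
// Draw order within a turn is fixed: reset, agent index, action choice,
// success. Uses R's RNG so set.seed() governs reproducibility.
//
// Returns the state bitmask after every turn and, optionally, a per-turn
// event log (reset flag, chosen agent 1-based or 0, action code
// 0 = exploit, 1 = search, 2 = copy, -1 = none/reset, success flag, N1
// after the turn).
// [[Rcpp::export]]
List sim_rmab_cpp(int N, double qC, double qI, double qO, NumericVector r,
                  int turns, bool record_events) {
  if (N < 1 || N > 30) stop("simulator supports 1 <= N <= 30");
  if (turns < 1) stop("'turns' must be >= 1");
  IntegerVector states(turns);
  IntegerMatrix ev;
  if (record_events) ev = IntegerMatrix(turns, 5);
  unsigned int sigma = 0;
  int N1 = 0;
  double p_reset = qC / N;
  RNGScope scope;
  for (int t = 0; t < turns; ++t) {
    int reset = 0, agent = 0, action = -1, success = 0;
    if (unif_rand() < p_reset) {
      sigma = 0; N1 = 0; reset = 1;
    } else {
      int n = (int)(unif_rand() * N);
      if (n >= N) n = N - 1;
      agent = n + 1;
      if ((sigma >> n) & 1u) {
        action = 0;  // informed: exploit, no state change
      } else {
        bool copy = unif_rand() < r[n];
        action = copy ? 2 : 1;
        double u = unif_rand();  // success draw always consumed
        if (copy ? (N1 >= 1 && u < qO) : (u < qI)) {
          success = 1;
          sigma |= (1u << n);
          ++N1;
        }
      }
    }
    states[t] = (int)sigma;
    if (record_events) {
      ev(t, 0) = reset; ev(t, 1) = agent; ev(t, 2) = action;
      ev(t, 3) = success; ev(t, 4) = N1;
    }
  }
  if (record_events)
    return List::create(_["states"] = states, _["events"] = ev);
  return List::create(_["states"] = states);
}
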