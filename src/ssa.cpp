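#include <Rcpp.h>
using namespace Rcpp;

// Direct-method stochastic simulation of the two-state gene.
// Channels: synthesis (rate k, ON only), removal (rate rho*n),
// ON->OFF (rate h), OFF->ON (rate f).  Two uniforms per event drawn
// from R's RNG stream so set.seed() gives bit-reproducible runs.
// Event kind codes: 1 = synthesis, 2 = removal, 3 = switch.
// [[Rcpp::export]]
List ssa_two_state(double k, double f, double h, double rho,
                   double t_max, int state0, int n0) {
  std::vector<double> times;
  std::vector<int> states, counts, kinds;
  size_t guess = (size_t)std::min(
      t_max * (k * f / (f + h) + rho * (k / rho) * f / (f + h) + f + h) + 1024.0,
      2e8);
  times.reserve(guess); states.reserve(guess);
  counts.reserve(guess); kinds.reserve(guess);

  double t = 0.0;
  int s = state0, n = n0;
  for (;;) {
    double a_syn = (s == 1) ? k : 0.0;
    double a_rem = rho * n;
    double a_sw  = (s == 1) ? h : f;
    double a0 = a_syn + a_rem + a_sw;
    if (a0 <= 0.0) break;
    double u1 = unif_rand();
    t += -std::log(u1) / a0;
    if (t > t_max) break;
    double u2 = unif_rand() * a0;
    int kind;
    if (u2 < a_syn) {
      n += 1; kind = 1;
    } else if (u2 < a_syn + a_rem) {
      n -= 1; kind = 2;
    } else {
      s = 1 - s; kind = 3;
    }
    times.push_back(t); states.push_back(s);
    counts.push_back(n); kinds.push_back(kind);
    if (times.size() % 1048576 == 0) checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["counts"] = counts, _["kinds"] = kinds);
}

// M-state promoter ladder: states 0..M-1, synthesis rate ks[state]
// (ks[0] = 0), transitions only between adjacent states with rates
// up[j] (j -> j+1) and down[j] (j+1 -> j), removal rate rho*n.
// [[Rcpp::export]]
List ssa_mstate(NumericVector ks, NumericVector up, NumericVector down,
                double rho, double t_max, int state0, int n0) {
  int M = ks.size();
  std::vector<double> times;
  std::vector<int> states, counts, kinds;
  double t = 0.0;
  int s = state0, n = n0;
  for (;;) {
    double a_syn = ks[s];
    double a_rem = rho * n;
    double a_up   = (s < M - 1) ? up[s] : 0.0;
    double a_down = (s > 0) ? down[s - 1] : 0.0;
    double a0 = a_syn + a_rem + a_up + a_down;
    if (a0 <= 0.0) break;
    double u1 = unif_rand();
    t += -std::log(u1) / a0;
    if (t > t_max) break;
    double u2 = unif_rand() * a0;
    int kind;
    if (u2 < a_syn) {
      n += 1; kind = 1;
    } else if (u2 < a_syn + a_rem) {
      n -= 1; kind = 2;
    } else if (u2 < a_syn + a_rem + a_up) {
      s += 1; kind = 3;
    } else {
      s -= 1; kind = 3;
    }
    times.push_back(t); states.push_back(s);
    counts.push_back(n); kinds.push_back(kind);
    if (times.size() % 1048576 == 0) checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["counts"] = counts, _["kinds"] = kinds);
}
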