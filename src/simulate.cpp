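#include <Rcpp.h>
using namespace Rcpp;

// Dual-route conflict accumulator, Euler-discretised at 1-ms steps.
//
// Evidence X starts at x0 (per-trial starting point, drawn by the caller)
// and evolves as
//   X <- X + mu*dt + s*(a(t+dt) - a(t)) + sigma*sqrt(dt)*eps,
// where a(t) = A*(t/tau)*exp(1 - t/tau) is a pulse of automatic,
// location-driven activation (peaks at t = tau with value A) and s is +1 on
// congruent, -1 on incongruent trials.  A response is emitted when |X| >= b;
// a positive crossing is the correct (instructed) response.  Trials that do
// not terminate within cap_ms are returned as NA (no response).
//
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List simulate_decisions_cpp(NumericVector mu, NumericVector s, NumericVector x0,
                            double A, double tau, double b, double sigma,
                            double cap_ms) {
  const int n = mu.size();
  if (s.size() != n || x0.size() != n) stop("mu, s and x0 must have equal length");
  const int cap = (int) cap_ms;
  IntegerVector time(n);
  IntegerVector side(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double x = x0[i];
    double a_prev = 0.0;
    int t_hit = NA_INTEGER, sd_hit = NA_INTEGER;
    for (int t = 1; t <= cap; ++t) {
      double a_t = A * (t / tau) * std::exp(1.0 - t / tau);
      x += mu[i] + s[i] * (a_t - a_prev) + sigma * norm_rand();
      a_prev = a_t;
      if (x >= b)  { t_hit = t; sd_hit = 1;  break; }
      if (x <= -b) { t_hit = t; sd_hit = -1; break; }
    }
    time[i] = t_hit;
    side[i] = sd_hit;
  }
  return List::create(_["decision_ms"] = time, _["sign"] = side);
}
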