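#include <Rcpp.h>
using namespace Rcpp;

// First-passage simulation of the superimposed diffusion process.
//
// Each trial follows an Euler-Maruyama discretisation
//   X(t + dt) = X(t) + mu(t) dt + sigma sqrt(dt) eps,   eps ~ N(0, 1)
// between absorbing boundaries at +b (correct) and -b (error). The
// time-varying drift mu(t) is precomputed in R at step midpoints and passed
// in as `drift`, one value per step. Uses R's RNG (norm_rand) so results are
// reproducible under set.seed().
//
// Returns response in {+1 correct, -1 error, 0 unabsorbed} and the decision
// time in ms (= max_steps * dt for unabsorbed walks).

// [[Rcpp::export(name = ".dmc_walk")]]
List dmc_walk(NumericVector drift, double b, double sigma, double dt,
              NumericVector z0, int max_steps) {
  int n = z0.size();
  if (drift.size() < max_steps)
    stop("drift schedule shorter than max_steps");
  IntegerVector resp(n);
  NumericVector dtime(n);
  const double sqdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = z0[i];
    int r = 0;
    int s = 0;
    for (; s < max_steps; ++s) {
      x += drift[s] * dt + sigma * sqdt * norm_rand();
      if (x >= b)  { r = 1;  ++s; break; }
      if (x <= -b) { r = -1; ++s; break; }
    }
    resp[i] = r;
    dtime[i] = s * dt;
  }
  return List::create(_["response"] = resp, _["decision_time"] = dtime);
}
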