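#include <Rcpp.h>
using namespace Rcpp;

// Slow-compartment CSF dynamics: dP/dt = E (P - P0) [I_net(t) - (P - P0)/R],
// I_net = I_ext + I_f + I_slow, with I_slow a reflected random walk bounded in
// [-islow_bound, islow_bound] that supplies the slow ("B-wave") ICP variance.
// Fixed-step RK4, one step per output sample; rate_mult > 1 dilates the slow
// dynamics for compressed-time protocols (cardiac/resp components are added in
// R on top of this trajectory and are not compressed).
//
// Returns the slow-pressure trajectory plus final state so protocols can be
// simulated phase by phase under one RNG stream.

static inline double rhs(double p, double inet, double E, double P0, double R) {
  double x = p - P0;
  return E * x * (inet - x / R);
}

// [[Rcpp::export(name = ".sim_slow_core")]]
List sim_slow_core(int n, double p_init, double islow_init,
                   NumericVector iext, double dt,
                   double E, double P0, double R, double If,
                   double islow_bound, double islow_sigma_step,
                   double rate_mult) {
  NumericVector p(n);
  double pc = p_init;
  double islow = islow_init;
  int clamped = 0;
  const double pfloor = P0 + 1e-6;

  for (int i = 0; i < n; ++i) {
    if (islow_bound > 0.0 && islow_sigma_step > 0.0) {
      islow += R::rnorm(0.0, islow_sigma_step);
      // reflect into [-bound, bound]
      if (islow > islow_bound)  islow =  2.0 * islow_bound - islow;
      if (islow < -islow_bound) islow = -2.0 * islow_bound - islow;
      if (islow > islow_bound)  islow =  islow_bound;   // pathological step
      if (islow < -islow_bound) islow = -islow_bound;
    }
    double inet = iext[i] + If + islow;
    // RK4 on the (possibly time-dilated) system dP/dt = rate_mult * f(P)
    double k1 = rate_mult * rhs(pc, inet, E, P0, R);
    double k2 = rate_mult * rhs(pc + 0.5 * dt * k1, inet, E, P0, R);
    double k3 = rate_mult * rhs(pc + 0.5 * dt * k2, inet, E, P0, R);
    double k4 = rate_mult * rhs(pc + dt * k3, inet, E, P0, R);
    pc += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (pc <= pfloor) { pc = pfloor; ++clamped; }
    p[i] = pc;
  }

  return List::create(_["p"] = p, _["p_final"] = pc,
                      _["islow_final"] = islow, _["n_clamped"] = clamped);
}
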