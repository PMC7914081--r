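#include <Rcpp.h>
using namespace Rcpp;

// Delay logistic integrator: dx/dt = mu * x(t - tau1) * (1 - x(t - tau2)/K),
// solved by the method of steps with fixed-step classical RK4.  Delayed
// lookups interpolate linearly on the already-resolved grid; the history is
// the constant x0 for t <= 0.  A zero delay uses the current stage value, so
// tau1 = tau2 = 0 reduces exactly to RK4 on the ordinary logistic equation.

struct DelayLookup {
  const std::vector<double>& x;
  double dt, x0;
  int i_now; // last fully resolved grid index

  double at(double s) const {
    if (s <= 0.0) return x0;
    double u = s / dt;
    int j = (int)std::floor(u);
    if (j >= i_now) return x[i_now]; // clamp inside the current step
    double w = u - j;
    return x[j] * (1.0 - w) + x[j + 1] * w;
  }
};

// [[Rcpp::export]]
List cpp_dde_logistic(double mu, double K, double tau1, double tau2,
                      double x0, double horizon, double dt) {
  int n = (int)std::floor(horizon / dt + 0.5);
  std::vector<double> x(n + 1);
  x[0] = x0;
  double guard = 1e8 * std::max(std::max(std::fabs(K), std::fabs(x0)), 1.0);
  int clamped = 0, diverged_at = -1;

  DelayLookup lk{x, dt, x0, 0};

  for (int i = 0; i < n; ++i) {
    lk.i_now = i;
    double t = i * dt;
    double xi = x[i];

    auto f = [&](double tt, double xs) {
      double x1 = tau1 == 0.0 ? xs : lk.at(tt - tau1);
      double x2 = tau2 == 0.0 ? xs : lk.at(tt - tau2);
      return mu * x1 * (1.0 - x2 / K);
    };

    double k1 = f(t, xi);
    double k2 = f(t + 0.5 * dt, xi + 0.5 * dt * k1);
    double k3 = f(t + 0.5 * dt, xi + 0.5 * dt * k2);
    double k4 = f(t + dt, xi + dt * k3);
    double xn = xi + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);

    if (!std::isfinite(xn) || std::fabs(xn) > guard) {
      diverged_at = i + 1;
      break;
    }
    if (xn < 0.0) { xn = 0.0; ++clamped; }
    x[i + 1] = xn;
  }

  return List::create(_["values"] = NumericVector(x.begin(), x.end()),
                      _["clamped"] = clamped,
                      _["diverged_at"] = diverged_at);
}
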