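#include <Rcpp.h>
using namespace Rcpp;

// Overdamped (Brownian) dynamics on the coupled double well
//   V(x, y) = h (x^2 - 1)^2 + y^2 / 2 + g x y
// integrated with Euler-Maruyama:
//   x' = x - dV/dx dt / gamma + sqrt(2 kT dt / gamma) xi
// Uses R's RNG so a set.seed() on the R side makes runs reproducible.
// [[Rcpp::export(name = ".dw_integrate")]]
List dw_integrate(int n_steps, double h, double g, double gamma,
                  double kT, double dt, double x0, double y0) {
  NumericVector x(n_steps + 1), y(n_steps + 1);
  x[0] = x0;
  y[0] = y0;
  const double pref = dt / gamma;
  const double amp = std::sqrt(2.0 * kT * dt / gamma);
  double xc = x0, yc = y0;
  for (int i = 1; i <= n_steps; ++i) {
    const double fx = 4.0 * h * xc * (xc * xc - 1.0) + g * yc;
    const double fy = yc + g * xc;
    xc += -fx * pref + amp * norm_rand();
    yc += -fy * pref + amp * norm_rand();
    if (std::fabs(xc) > 10.0)
      stop("trajectory diverged (|x| > 10) at step %d; use a smaller dt", i);
    x[i] = xc;
    y[i] = yc;
  }
  return List::create(_["x"] = x, _["y"] = y);
}
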