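#include <Rcpp.h>
#include <cmath>

// Two-compartment IV-infusion system with time-varying clearance.
// State: A1 (central amount, mg), A2 (peripheral amount, mg).
// Integrated with an adaptive Dormand-Prince RK45; the kinetics are
// non-stiff (time constants of hours to weeks), so explicit RK with PI
// step control is appropriate.

namespace {

struct Model {
  double rate, v1, v2, q;
  double cl_base, emax, t50, hill;
  bool exp_form;

  inline double cl(double t) const {
    double s = 0.0;
    if (t > 0.0) {
      double th = std::pow(t, hill);
      s = th / (std::pow(t50, hill) + th);
    }
    if (exp_form) return cl_base * std::exp(emax * s);
    double f = 1.0 + emax * s;
    return cl_base * (f > 1e-6 ? f : 1e-6);
  }

  inline void deriv(double t, const double y[2], double dy[2]) const {
    double clt = cl(t);
    dy[0] = rate - (clt / v1) * y[0] - (q / v1) * y[0] + (q / v2) * y[1];
    dy[1] = (q / v1) * y[0] - (q / v2) * y[1];
  }
};

// Dormand-Prince 5(4) coefficients
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
             e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

// integrate y over [t, t_end]; returns false on step failure
bool advance(const Model &m, double &t, double t_end, double y[2],
             double rtol, double atol, double &h) {
  const int max_steps = 200000;
  int steps = 0;
  double k1[2], k2[2], k3[2], k4[2], k5[2], k6[2], k7[2];
  double yt[2], y5[2], y4[2];
  m.deriv(t, y, k1);
  while (t < t_end) {
    if (++steps > max_steps) return false;
    if (h > t_end - t) h = t_end - t;
    for (int i = 0; i < 2; ++i) yt[i] = y[i] + h * a21 * k1[i];
    m.deriv(t + c2 * h, yt, k2);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    m.deriv(t + c3 * h, yt, k3);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    m.deriv(t + c4 * h, yt, k4);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    m.deriv(t + c5 * h, yt, k5);
    for (int i = 0; i < 2; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    m.deriv(t + h, yt, k6);
    for (int i = 0; i < 2; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    m.deriv(t + h, y5, k7);
    for (int i = 0; i < 2; ++i)
      y4[i] = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                          e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
    double err = 0.0;
    for (int i = 0; i < 2; ++i) {
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = (y5[i] - y4[i]) / sc;
      err += e * e;
    }
    err = std::sqrt(err / 2.0);
    if (!std::isfinite(err)) return false;
    if (err <= 1.0) {
      t += h;
      y[0] = y5[0];
      y[1] = y5[1];
      k1[0] = k7[0];
      k1[1] = k7[1];
    }
    double fac = 0.9 * std::pow(err > 1e-10 ? err : 1e-10, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h < 1e-10) return false;
  }
  return true;
}

} // namespace

// [[Rcpp::export(name = ".pk_integrate_cpp")]]
Rcpp::NumericMatrix pk_integrate_cpp(Rcpp::NumericVector state, double t0,
                                     Rcpp::NumericVector tout, double rate,
                                     double cl_base, double emax, double t50,
                                     double hill, double v1, double v2,
                                     double q, bool exp_form, double rtol,
                                     double atol) {
  Model m{rate, v1, v2, q, cl_base, emax, t50, hill, exp_form};
  int n = tout.size();
  Rcpp::NumericMatrix out(n, 2);
  double y[2] = {state[0], state[1]};
  double t = t0;
  double h = (tout[n - 1] - t0) / 10.0;
  if (h <= 0) h = 1e-3;
  for (int j = 0; j < n; ++j) {
    if (tout[j] > t) {
      if (!advance(m, t, tout[j], y, rtol, atol, h))
        Rcpp::stop("ODE integration failed between t=%g and t=%g h", t,
                   tout[j]);
    }
    out(j, 0) = y[0];
    out(j, 1) = y[1];
  }
  return out;
}
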