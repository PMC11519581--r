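// Adaptive embedded Runge-Kutta (Dormand-Prince 5(4)) integrator with
// hard-coded right-hand sides for the three fixture models, plus an
// R-callback path for user-defined models. Step size is clamped so the
// solver lands exactly on every requested output time.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// model ids: 1 = Lotka-Volterra, 2 = repressilator, 3 = viral life cycle
static inline void rhs_fixture(int model, double t, const double* y,
                               const double* th, double* dy) {
  (void)t;
  switch (model) {
  case 1: { // theta = (a, b, c, delta)
    const double x = y[0], p = y[1];
    dy[0] = th[0] * x - th[1] * x * p;
    dy[1] = th[2] * x * p - th[3] * p;
    break;
  }
  case 2: { // theta = (k1, K, n, dA, dB, dC); cyclic repression C -| A -| B? no:
    // A repressed by C, B repressed by A, C repressed by B
    const double k1 = th[0], K = th[1], n = th[2];
    const double A = y[0], B = y[1], C = y[2];
    const double hC = std::pow(std::max(C, 0.0) / K, n);
    const double hA = std::pow(std::max(A, 0.0) / K, n);
    const double hB = std::pow(std::max(B, 0.0) / K, n);
    dy[0] = k1 / (1.0 + hC) - th[3] * A;
    dy[1] = k1 / (1.0 + hA) - th[4] * B;
    dy[2] = k1 / (1.0 + hB) - th[5] * C;
    break;
  }
  case 3: { // theta = (k_t, f, d_p, k_m, d_m, k_p, d_r, k_a, K_r, k_e, d_v)
    const double Rp = y[0], Rm = y[1], Pn = y[2], Ps = y[3], Rv = y[4], V = y[5];
    const double kt = th[0], f = th[1], dp = th[2], km = th[3], dm = th[4];
    const double kp = th[5], dr = th[6], ka = th[7], Kr = th[8], ke = th[9],
                 dv = th[10];
    // shared ribosome/polymerase occupancy saturates in genomic (+)RNA
    const double sat = std::max(Rp, 0.0) / (Kr + std::max(Rp, 0.0));
    const double trans = kt * sat;
    const double pack = ka * Ps * sat;
    dy[0] = kp * Pn * Rm - dr * Rp - pack;
    dy[1] = km * Pn * sat - dm * Rm;
    dy[2] = f * trans - dp * Pn;
    dy[3] = (1.0 - f) * trans - dp * Ps;
    dy[4] = pack - ke * Rv;
    dy[5] = ke * Rv - dv * V;
    break;
  }
  default:
    Rcpp::stop("unknown fixture model id");
  }
}

// Dormand-Prince tableau
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// 4th-order embedded weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
                    e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

struct OdeFailure {};

// integrate one trajectory; writes rows of `out` (ntimes x ns, column-major
// via out[j + i*nt]); throws OdeFailure on step underflow or state blow-up
static void rk45_core(int model, const double* th, std::vector<double>& y,
                      double t0, const double* times, int nt, int ns,
                      double rtol, double atol, int max_steps, double* out,
                      int ldout) {
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns), k7(ns),
      ytmp(ns), ynew(ns), err(ns);
  double t = t0;
  int next = 0;
  // emit any output times equal to t0
  while (next < nt && times[next] <= t0 + 1e-14 * std::max(1.0, std::fabs(t0))) {
    for (int s = 0; s < ns; ++s) out[next + s * ldout] = y[s];
    ++next;
  }
  if (next >= nt) return;
  double tend = times[nt - 1];
  double h = std::min(1e-3 * std::max(tend - t0, 1e-8), times[next] - t);
  rhs_fixture(model, t, y.data(), th, k1.data());
  int steps = 0;
  while (next < nt) {
    if (++steps > max_steps) throw OdeFailure();
    bool hit = false;
    if (t + h >= times[next] - 1e-12 * std::max(1.0, std::fabs(times[next]))) {
      h = times[next] - t;
      hit = true;
    }
    if (h < 1e-14 * std::max(1.0, std::fabs(t))) throw OdeFailure();
    for (int s = 0; s < ns; ++s) ytmp[s] = y[s] + h * a21 * k1[s];
    rhs_fixture(model, t + c2 * h, ytmp.data(), th, k2.data());
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a31 * k1[s] + a32 * k2[s]);
    rhs_fixture(model, t + c3 * h, ytmp.data(), th, k3.data());
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a41 * k1[s] + a42 * k2[s] + a43 * k3[s]);
    rhs_fixture(model, t + c4 * h, ytmp.data(), th, k4.data());
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a51 * k1[s] + a52 * k2[s] + a53 * k3[s] + a54 * k4[s]);
    rhs_fixture(model, t + c5 * h, ytmp.data(), th, k5.data());
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a61 * k1[s] + a62 * k2[s] + a63 * k3[s] +
                            a64 * k4[s] + a65 * k5[s]);
    rhs_fixture(model, t + h, ytmp.data(), th, k6.data());
    for (int s = 0; s < ns; ++s)
      ynew[s] = y[s] + h * (b1 * k1[s] + b3 * k3[s] + b4 * k4[s] + b5 * k5[s] +
                            b6 * k6[s]);
    rhs_fixture(model, t + h, ynew.data(), th, k7.data());
    double enorm = 0.0;
    for (int s = 0; s < ns; ++s) {
      double y4 = y[s] + h * (e1 * k1[s] + e3 * k3[s] + e4 * k4[s] +
                              e5 * k5[s] + e6 * k6[s] + e7 * k7[s]);
      double sc = atol + rtol * std::max(std::fabs(y[s]), std::fabs(ynew[s]));
      double e = (ynew[s] - y4) / sc;
      enorm += e * e;
    }
    enorm = std::sqrt(enorm / ns);
    if (!std::isfinite(enorm)) throw OdeFailure();
    if (enorm <= 1.0) { // accept
      t += h;
      y.swap(ynew);
      k1.swap(k7); // FSAL
      for (int s = 0; s < ns; ++s)
        if (std::fabs(y[s]) > 1e12) throw OdeFailure();
      if (hit) {
        while (next < nt &&
               std::fabs(times[next] - t) <=
                   1e-9 * std::max(1.0, std::fabs(t))) {
          for (int s = 0; s < ns; ++s) out[next + s * ldout] = y[s];
          ++next;
        }
      }
    }
    double fac = enorm > 0 ? 0.9 * std::pow(enorm, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (next < nt && t + h > times[next]) h = times[next] - t;
    if (h <= 0) h = 1e-12;
  }
}

static int n_states_fixture(int model) {
  if (model == 1) return 2;
  if (model == 2) return 3;
  if (model == 3) return 6;
  Rcpp::stop("unknown fixture model id");
}

// [[Rcpp::export]]
NumericMatrix ode_solve_fixture(int model, NumericVector theta,
                                NumericVector y0, NumericVector times,
                                double t0, double rtol, double atol,
                                int max_steps) {
  int ns = n_states_fixture(model);
  int nt = times.size();
  if ((int)y0.size() != ns) stop("y0 length does not match model state count");
  NumericMatrix out(nt, ns);
  std::vector<double> y(y0.begin(), y0.end());
  try {
    rk45_core(model, theta.begin(), y, t0, times.begin(), nt, ns, rtol, atol,
              max_steps, out.begin(), nt);
  } catch (OdeFailure&) {
    stop("ODE integration failed (step underflow or state blow-up)");
  }
  return out;
}

// batch over parameter rows; failures yield NaN rows and ok[i] = FALSE
// [[Rcpp::export]]
List ode_solve_fixture_batch(int model, NumericMatrix thetas, NumericVector y0,
                             NumericVector times, double t0, double rtol,
                             double atol, int max_steps) {
  int ns = n_states_fixture(model);
  int nt = times.size();
  int n = thetas.nrow();
  if ((int)y0.size() != ns) stop("y0 length does not match model state count");
  NumericVector arr(Dimension(n, nt, ns));
  LogicalVector ok(n);
  std::vector<double> buf(nt * ns), th(thetas.ncol());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < thetas.ncol(); ++j) th[j] = thetas(i, j);
    std::vector<double> y(y0.begin(), y0.end());
    bool good = true;
    try {
      rk45_core(model, th.data(), y, t0, times.begin(), nt, ns, rtol, atol,
                max_steps, buf.data(), nt);
    } catch (OdeFailure&) {
      good = false;
    }
    ok[i] = good;
    for (int s = 0; s < ns; ++s)
      for (int j = 0; j < nt; ++j)
        arr[i + n * (j + nt * s)] = good ? buf[j + s * nt] : NA_REAL;
  }
  return List::create(_["states"] = arr, _["ok"] = ok);
}

// R-callback integrator for user-defined / SBML-imported models (slow path)
// [[Rcpp::export]]
NumericMatrix ode_solve_r(Function rhs, NumericVector theta, NumericVector y0,
                          NumericVector times, double t0, double rtol,
                          double atol, int max_steps) {
  int ns = y0.size();
  int nt = times.size();
  NumericMatrix out(nt, ns);

  std::vector<double> y(y0.begin(), y0.end());
  auto deriv = [&](double t, const std::vector<double>& yy,
                   std::vector<double>& dy) {
    NumericVector yv(yy.begin(), yy.end());
    NumericVector d = rhs(t, yv, theta);
    if ((int)d.size() != ns) stop("rhs returned wrong length");
    for (int s = 0; s < ns; ++s) dy[s] = d[s];
  };

  // simple non-FSAL adaptive loop mirroring rk45_core
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), k5(ns), k6(ns), k7(ns),
      ytmp(ns), ynew(ns);
  double t = t0;
  int next = 0;
  while (next < nt && times[next] <= t0 + 1e-14 * std::max(1.0, std::fabs(t0))) {
    for (int s = 0; s < ns; ++s) out(next, s) = y[s];
    ++next;
  }
  if (next >= nt) return out;
  double tend = times[nt - 1];
  double h = std::min(1e-3 * std::max(tend - t0, 1e-8), times[next] - t);
  deriv(t, y, k1);
  int steps = 0;
  while (next < nt) {
    if (++steps > max_steps)
      stop("ODE integration failed (max step count exceeded)");
    bool hit = false;
    if (t + h >= times[next] - 1e-12 * std::max(1.0, std::fabs(times[next]))) {
      h = times[next] - t;
      hit = true;
    }
    if (h < 1e-14 * std::max(1.0, std::fabs(t)))
      stop("ODE integration failed (step underflow)");
    for (int s = 0; s < ns; ++s) ytmp[s] = y[s] + h * a21 * k1[s];
    deriv(t + c2 * h, ytmp, k2);
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a31 * k1[s] + a32 * k2[s]);
    deriv(t + c3 * h, ytmp, k3);
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a41 * k1[s] + a42 * k2[s] + a43 * k3[s]);
    deriv(t + c4 * h, ytmp, k4);
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a51 * k1[s] + a52 * k2[s] + a53 * k3[s] + a54 * k4[s]);
    deriv(t + c5 * h, ytmp, k5);
    for (int s = 0; s < ns; ++s)
      ytmp[s] = y[s] + h * (a61 * k1[s] + a62 * k2[s] + a63 * k3[s] +
                            a64 * k4[s] + a65 * k5[s]);
    deriv(t + h, ytmp, k6);
    for (int s = 0; s < ns; ++s)
      ynew[s] = y[s] + h * (b1 * k1[s] + b3 * k3[s] + b4 * k4[s] + b5 * k5[s] +
                            b6 * k6[s]);
    deriv(t + h, ynew, k7);
    double enorm = 0.0;
    for (int s = 0; s < ns; ++s) {
      double y4 = y[s] + h * (e1 * k1[s] + e3 * k3[s] + e4 * k4[s] +
                              e5 * k5[s] + e6 * k6[s] + e7 * k7[s]);
      double sc = atol + rtol * std::max(std::fabs(y[s]), std::fabs(ynew[s]));
      double e = (ynew[s] - y4) / sc;
      enorm += e * e;
    }
    enorm = std::sqrt(enorm / ns);
    if (!std::isfinite(enorm))
      stop("ODE integration failed (non-finite error estimate)");
    if (enorm <= 1.0) {
      t += h;
      y = ynew;
      k1 = k7;
      for (int s = 0; s < ns; ++s)
        if (std::fabs(y[s]) > 1e12)
          stop("ODE integration failed (state blow-up)");
      if (hit) {
        while (next < nt &&
               std::fabs(times[next] - t) <=
                   1e-9 * std::max(1.0, std::fabs(t))) {
          for (int s = 0; s < ns; ++s) out(next, s) = y[s];
          ++next;
        }
      }
    }
    double fac = enorm > 0 ? 0.9 * std::pow(enorm, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (next < nt && t + h > times[next]) h = times[next] - t;
    if (h <= 0) h = 1e-12;
  }
  return out;
}
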