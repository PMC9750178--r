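// Axisymmetric Helfrich shape-equation integrator.
//
// The free membrane of a closed vesicle surrounding a rigid spherical cap is
// parameterized by arclength s from the pole opposite the cap:
//   r'   = cos(psi)
//   psi' = u
// with u the meridional curvature, c2 = sin(psi)/r the azimuthal curvature,
// and w = u + sin(psi)/r = c1 + c2.  Stationarity of
//   (kappa/2) \int w^2 dA + sigma * Area
// (sigma the area-constraint multiplier) gives, with kappa = 1 and lengths in
// units of the vesicle radius,
//   u'   = gamma sin(psi)/r - u cos(psi)/r + sin(psi) cos(psi)/r^2
//   gam' = (u^2 - sin(psi)^2/r^2)/2 + sigma
// where gamma is the multiplier conjugate to the constraint r' = cos(psi);
// gamma(0) = 0 at a regular pole.  Area and bending energy are accumulated as
//   A' = 2 pi r,   E' = pi r w^2.
// The integrator is a standard adaptive Dormand-Prince RK5(4) pair; shooting
// over (u0, sigma, L) is driven from R.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void rhs(const double y[6], double dy[6], double sigma) {
  const double psi = y[0], u = y[1], gam = y[2], r = y[3];
  const double sp = std::sin(psi), cp = std::cos(psi);
  const double w = u + sp / r;
  dy[0] = u;
  dy[1] = gam * sp / r - u * cp / r + sp * cp / (r * r);
  dy[2] = 0.5 * (u * u - sp * sp / (r * r)) + sigma;
  dy[3] = cp;
  dy[4] = 2.0 * M_PI * r;
  dy[5] = M_PI * r * w * w;
}

// Dormand-Prince coefficients
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
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Integrate from a series start near the pole out to arclength L.
// Returns (psi, u, gamma, r, area, energy, ok, nsteps).
// [[Rcpp::export]]
NumericVector helfrich_shoot(double u0, double sigma, double L,
                             double tol = 1e-11) {
  const double s0 = 1e-7;
  const double a3 = sigma * u0 / 8.0;   // psi ~ u0 s + a3 s^3 near the pole
  double y[6];
  y[0] = u0 * s0 + a3 * s0 * s0 * s0;
  y[1] = u0 + 3.0 * a3 * s0 * s0;
  y[2] = sigma * s0;
  y[3] = s0 - u0 * u0 * s0 * s0 * s0 / 6.0;
  y[4] = M_PI * s0 * s0;
  y[5] = 2.0 * M_PI * u0 * u0 * s0 * s0;

  double s = s0, h = 1e-4 * L;
  int ok = 1;
  long nstep = 0;
  double k1[6], k2[6], k3[6], k4[6], k5[6], k6[6], k7[6], yt[6], y5[6];
  rhs(y, k1, sigma);
  while (s < L) {
    if (h > L - s) h = L - s;
    for (int i = 0; i < 6; i++) yt[i] = y[i] + h * a21 * k1[i];
    rhs(yt, k2, sigma);
    for (int i = 0; i < 6; i++)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(yt, k3, sigma);
    for (int i = 0; i < 6; i++)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(yt, k4, sigma);
    for (int i = 0; i < 6; i++)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    rhs(yt, k5, sigma);
    for (int i = 0; i < 6; i++)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs(yt, k6, sigma);
    for (int i = 0; i < 6; i++)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    rhs(y5, k7, sigma);
    double err = 0.0;
    for (int i = 0; i < 6; i++) {
      double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * k7[i]);
      double sc = tol + tol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double q = ei / sc;
      err += q * q;
    }
    err = std::sqrt(err / 6.0);
    if (err <= 1.0 || h < 1e-14 * L) {
      s += h;
      for (int i = 0; i < 6; i++) y[i] = y5[i];
      for (int i = 0; i < 6; i++) k1[i] = k7[i];  // FSAL
      if (y[3] < 1e-10 || !std::isfinite(y[3]) || std::fabs(y[1]) > 1e10) {
        ok = 0;
        break;
      }
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (++nstep > 4000000) { ok = 0; break; }
  }
  return NumericVector::create(y[0], y[1], y[2], y[3], y[4], y[5],
                               (double)ok, (double)nstep);
}

// Same integration but storing the meridian at n equally spaced arclengths
// (for shape output / independent energy quadrature).  Fixed-step RK4 at a
// resolution chosen by the caller; accuracy is for plotting and
// cross-checking, not for the shooting residuals.
// [[Rcpp::export]]
NumericMatrix helfrich_trace(double u0, double sigma, double L, int n = 2000) {
  const double s0 = 1e-7;
  const double a3 = sigma * u0 / 8.0;
  double y[6];
  y[0] = u0 * s0 + a3 * s0 * s0 * s0;
  y[1] = u0 + 3.0 * a3 * s0 * s0;
  y[2] = sigma * s0;
  y[3] = s0 - u0 * u0 * s0 * s0 * s0 / 6.0;
  y[4] = M_PI * s0 * s0;
  y[5] = 2.0 * M_PI * u0 * u0 * s0 * s0;
  NumericMatrix out(n + 1, 7);
  const int sub = 40;
  double s = s0;
  double k1[6], k2[6], k3[6], k4[6], yt[6];
  out(0, 0) = s;
  for (int j = 0; j < 6; j++) out(0, j + 1) = y[j];
  for (int i = 1; i <= n; i++) {
    double stgt = s0 + (L - s0) * i / n;
    double h = (stgt - s) / sub;
    for (int m = 0; m < sub; m++) {
      rhs(y, k1, sigma);
      for (int j = 0; j < 6; j++) yt[j] = y[j] + 0.5 * h * k1[j];
      rhs(yt, k2, sigma);
      for (int j = 0; j < 6; j++) yt[j] = y[j] + 0.5 * h * k2[j];
      rhs(yt, k3, sigma);
      for (int j = 0; j < 6; j++) yt[j] = y[j] + h * k3[j];
      rhs(yt, k4, sigma);
      for (int j = 0; j < 6; j++)
        y[j] += h / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
      s += h;
    }
    out(i, 0) = s;
    for (int j = 0; j < 6; j++) out(i, j + 1) = y[j];
  }
  colnames(out) = CharacterVector::create("s", "psi", "u", "gamma", "r",
                                          "area", "energy");
  return out;
}
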