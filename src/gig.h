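#ifndef CSPRS_GIG_H
#define CSPRS_GIG_H

#include <Rmath.h>
#include <R.h>
#include <cmath>
#include <algorithm>

// Generalized inverse Gaussian sampling.
//
// Density convention used throughout the package:
//   GIG(p, chi, psi):  f(x) propto x^{p-1} exp(-(chi/x + psi*x)/2),  x > 0.
// Degenerate limits: chi = 0, p > 0 -> Gamma(p, rate psi/2);
//                    psi = 0, p < 0 -> InvGamma(-p, rate chi/2).
// The general case uses Devroye's (2014) uniformly fast rejection sampler
// for the two-parameter form f(x) propto x^{lam-1} exp(-omega (x + 1/x)/2).

namespace csprs {

inline double gig_psi_fn(double x, double alpha, double lam) {
  return -alpha * (std::cosh(x) - 1.0) - lam * (std::exp(x) - x - 1.0);
}

inline double gig_dpsi_fn(double x, double alpha, double lam) {
  return -alpha * std::sinh(x) - lam * (std::exp(x) - 1.0);
}

// One draw from the two-parameter GIG(lam, omega), omega > 0.
inline double rgig_two_param(double lam, double omega) {
  bool swap = false;
  if (lam < 0.0) { lam = -lam; swap = true; }
  const double alpha = std::sqrt(omega * omega + lam * lam) - lam;

  double t, s;
  double x = -gig_psi_fn(1.0, alpha, lam);
  if (x >= 0.5 && x <= 2.0) {
    t = 1.0;
  } else if (x > 2.0) {
    t = std::sqrt(2.0 / (alpha + lam));
  } else {
    t = std::log(4.0 / (alpha + 2.0 * lam));
  }

  x = -gig_psi_fn(-1.0, alpha, lam);
  if (x >= 0.5 && x <= 2.0) {
    s = 1.0;
  } else if (x > 2.0) {
    s = std::sqrt(4.0 / (alpha * std::cosh(1.0) + lam));
  } else {
    double s1 = (lam > 0.0) ? 1.0 / lam : R_PosInf;
    double s2 = (alpha > 0.0)
      ? std::log(1.0 + 1.0 / alpha + std::sqrt(1.0 / (alpha * alpha) + 2.0 / alpha))
      : R_PosInf;
    s = std::min(s1, s2);
  }

  const double eta   = -gig_psi_fn(t, alpha, lam);
  const double zeta  = -gig_dpsi_fn(t, alpha, lam);
  const double theta = -gig_psi_fn(-s, alpha, lam);
  const double xi    =  gig_dpsi_fn(-s, alpha, lam);
  const double pp = 1.0 / xi;
  const double rr = 1.0 / zeta;
  const double td = t - rr * eta;
  const double sd = s - pp * theta;
  const double q  = td + sd;

  double rnd = 0.0;
  for (;;) {
    const double U = unif_rand();
    const double V = unif_rand();
    const double W = unif_rand();
    if (U < q / (pp + q + rr)) {
      rnd = -sd + q * V;
    } else if (U < (q + rr) / (pp + q + rr)) {
      rnd = td - rr * std::log(V);
    } else {
      rnd = -sd + pp * std::log(V);
    }
    double g = 1.0;
    if (rnd > td) {
      g = std::exp(-eta - zeta * (rnd - t));
    } else if (rnd < -sd) {
      g = std::exp(-theta + xi * (rnd + s));
    }
    if (W * g <= std::exp(gig_psi_fn(rnd, alpha, lam))) break;
  }

  double out = std::exp(rnd) * (lam / omega + std::sqrt(1.0 + (lam / omega) * (lam / omega)));
  if (swap) out = 1.0 / out;
  return out;
}

// Inverse-Gaussian IG(mu, lambda) draw (Michael, Schucany & Haas), written
// with the cancellation-free smaller-root form so extreme mu/lambda ratios
// stay accurate.
inline double rinvgauss(double mu, double lambda) {
  const double z = norm_rand();
  const double y = z * z;
  const double t = mu * y / (2.0 * lambda);
  const double x = mu / (1.0 + t + std::sqrt(t * t + 2.0 * t));
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// One draw from GIG(p, chi, psi) in the three-parameter density convention.
inline double rgig(double p, double chi, double psi) {
  const double eps = 1e-200;
  if (chi < 0.0 || psi < 0.0) Rf_error("rgig: chi and psi must be non-negative");
  if (chi <= eps && psi <= eps) Rf_error("rgig: chi and psi cannot both be zero");
  if (chi <= eps) {
    if (p <= 0.0) Rf_error("rgig: chi = 0 requires p > 0");
    return R::rgamma(p, 2.0 / psi);          // shape, scale
  }
  if (psi <= eps) {
    if (p >= 0.0) Rf_error("rgig: psi = 0 requires p < 0");
    return (chi / 2.0) / R::rgamma(-p, 1.0); // inverse-gamma via gamma
  }
  const double omega = std::sqrt(chi * psi);
  // |p| = 1/2 is (reciprocal) inverse Gaussian; this is the hot path for the
  // default prior shape a = 1 (p = a - 1/2).
  if (omega > 1e-8) {
    if (p == -0.5) return rinvgauss(std::sqrt(chi / psi), chi);
    if (p == 0.5)  return 1.0 / rinvgauss(std::sqrt(psi / chi), psi);
  }
  return rgig_two_param(p, omega) * std::sqrt(chi / psi);
}

} // namespace csprs

#endif
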