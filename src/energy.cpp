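#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dimensionless Helfrich energy of an axisymmetric tube profile.
//
// The meridian is parameterized by the tangent angle psi on a uniform
// arc-length grid of n nodes.  Conventions (units: lengths in R, energy in
// kappa): dz/ds = cos(psi), dr/ds = -sin(psi); meridional curvature
// c_m = dpsi/ds, circumferential c_c = cos(psi)/r; a straight cylinder has
// psi == 0 and total curvature J = 1.  The clamped boundary radius is 1.
//
// The total arc length S is eliminated analytically through the axial
// closure sum_i w_i cos(psi_i) * h = L (trapezoid weights w, h = S/(n-1)),
// so the only remaining closure constraint is radial: g = r_n - 1 = 0.
//
// The pressure work term is p * V_strip with V_strip the volume enclosed in
// a fixed axial window [zc - w/2, zc + w/2], computed as the line integral
// pi * int r^2 dz over the clipped meridian (signed, so overhanging
// profiles are handled).  An optional lateral-tension term sig * A_total
// is included for sensitivity scenarios (sig = 0 in the baseline model).

namespace {

struct Eval {
  double E, FB, V, Vtot, A, Astrip, S, g;
  bool feasible;
};

Eval eval_core(const double* psi, int n, double L, double wwin, double zc,
               double p, double sig,
               std::vector<double>* r_out = nullptr,
               std::vector<double>* z_out = nullptr) {
  Eval out;
  out.feasible = true;
  out.FB = out.V = out.Vtot = out.A = out.Astrip = out.S = out.g = 0.0;

  std::vector<double> sn(n), cs(n), r(n), z(n);
  for (int i = 0; i < n; ++i) {
    sn[i] = std::sin(psi[i]);
    cs[i] = std::cos(psi[i]);
  }
  double cw = 0.5 * (cs[0] + cs[n - 1]);
  for (int i = 1; i < n - 1; ++i) cw += cs[i];
  // axial closure needs a positive net advance; heavily folded states are
  // outside the tracked branch and are pushed back by a smooth penalty
  if (cw < 0.05 * (n - 1)) {
    out.feasible = false;
    out.E = 1e8 + 1e4 * (0.05 * (n - 1) - cw);
    return out;
  }
  double S = L * (n - 1) / cw;
  double h = S / (n - 1);
  out.S = S;

  r[0] = 1.0;
  z[0] = 0.0;
  for (int i = 1; i < n; ++i) {
    r[i] = r[i - 1] - 0.5 * h * (sn[i - 1] + sn[i]);
    z[i] = z[i - 1] + 0.5 * h * (cs[i - 1] + cs[i]);
  }
  out.g = r[n - 1] - 1.0;
  if (r_out) *r_out = r;
  if (z_out) *z_out = z;

  const double rfloor = 1e-3;
  double pen = 0.0;
  for (int i = 0; i < n; ++i)
    if (r[i] < rfloor) pen += (rfloor - r[i]);
  if (pen > 0.0) {
    out.feasible = false;
    out.E = 1e6 * (1.0 + pen);
    return out;
  }

  double FB = 0.0, A = 0.0;
  for (int i = 0; i < n; ++i) {
    double cm;
    if (i == 0)
      cm = (psi[1] - psi[0]) / h;
    else if (i == n - 1)
      cm = (psi[n - 1] - psi[n - 2]) / h;
    else
      cm = (psi[i + 1] - psi[i - 1]) / (2.0 * h);
    double J = cm + cs[i] / r[i];
    double wq = (i == 0 || i == n - 1) ? 0.5 : 1.0;
    double dA = 2.0 * M_PI * r[i] * h * wq;
    FB += 0.5 * J * J * dA;
    A += dA;
  }
  out.FB = FB;
  out.A = A;

  const double za = zc - 0.5 * wwin, zb = zc + 0.5 * wwin;
  double V = 0.0, As = 0.0, Vtot = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    double z0 = z[i], z1 = z[i + 1], r0 = r[i], r1 = r[i + 1];
    double dz = z1 - z0, dr = r1 - r0;
    Vtot += dz * (r0 * r0 + r0 * r1 + r1 * r1) / 3.0;
    if (dz == 0.0) {
      if (z0 > za && z0 < zb) As += 0.5 * (r0 + r1) * h;
      continue;
    }
    double ta = (za - z0) / dz, tb = (zb - z0) / dz;
    double t0 = std::max(0.0, std::min(ta, tb));
    double t1 = std::min(1.0, std::max(ta, tb));
    if (t1 <= t0) continue;
    // int (r0 + dr t)^2 dt and int (r0 + dr t) dt on [t0, t1], exact
    double q2 = r0 * r0 * (t1 - t0) + r0 * dr * (t1 * t1 - t0 * t0) +
                dr * dr * (t1 * t1 * t1 - t0 * t0 * t0) / 3.0;
    double q1 = r0 * (t1 - t0) + 0.5 * dr * (t1 * t1 - t0 * t0);
    V += dz * q2;
    As += h * q1;
  }
  out.V = M_PI * V;
  out.Vtot = M_PI * Vtot;
  out.Astrip = 2.0 * M_PI * As;
  out.E = FB + p * out.V + sig * A;
  return out;
}

void fill_full(const NumericVector& psi_int, std::vector<double>& psi) {
  int n = psi_int.size() + 2;
  psi.resize(n);
  psi[0] = 0.0;
  psi[n - 1] = 0.0;
  for (int i = 0; i < n - 2; ++i) psi[i + 1] = psi_int[i];
}

}  // namespace

// [[Rcpp::export]]
List helfrich_eval(NumericVector psi, double L, double wwin, double zc,
                   double p, double sig) {
  int n = psi.size();
  std::vector<double> r, z;
  Eval ev = eval_core(REAL(psi), n, L, wwin, zc, p, sig, &r, &z);
  return List::create(
      _["E"] = ev.E, _["F_B"] = ev.FB, _["V_strip"] = ev.V,
      _["V_tot"] = ev.Vtot,
      _["area"] = ev.A, _["A_strip"] = ev.Astrip, _["S"] = ev.S,
      _["g"] = ev.g, _["feasible"] = ev.feasible,
      _["r"] = ev.feasible ? NumericVector(r.begin(), r.end())
                           : NumericVector(0),
      _["z"] = ev.feasible ? NumericVector(z.begin(), z.end())
                           : NumericVector(0));
}

// Augmented-Lagrangian objective on the interior tangent angles (ends
// clamped to zero): Phi = E + lam * g + mu/2 * g^2 for the radial closure
// g = r_n - 1, plus, when vfix > 0 (volume-conserving variant),
// lam2 * gv + mu2/2 * gv^2 for the enclosed-volume constraint
// gv = V_tot - vfix.
// [[Rcpp::export]]
double helfrich_objective(NumericVector psi_int, double L, double wwin,
                          double zc, double p, double sig, double lam,
                          double mu, double vfix = -1.0, double lam2 = 0.0,
                          double mu2 = 0.0) {
  std::vector<double> psi;
  fill_full(psi_int, psi);
  Eval ev = eval_core(psi.data(), (int)psi.size(), L, wwin, zc, p, sig);
  double phi = ev.E + lam * ev.g + 0.5 * mu * ev.g * ev.g;
  if (vfix > 0.0 && ev.feasible) {
    double gv = ev.Vtot - vfix;
    phi += lam2 * gv + 0.5 * mu2 * gv * gv;
  }
  return phi;
}

// Central-difference gradient of the objective with respect to the
// interior tangent angles.
// [[Rcpp::export]]
NumericVector helfrich_objective_grad(NumericVector psi_int, double L,
                                      double wwin, double zc, double p,
                                      double sig, double lam, double mu,
                                      double vfix = -1.0, double lam2 = 0.0,
                                      double mu2 = 0.0, double eps = 1e-6) {
  int m = psi_int.size();
  std::vector<double> psi;
  fill_full(psi_int, psi);
  int n = (int)psi.size();
  NumericVector grad(m);
  auto phi_of = [&]() {
    Eval ev = eval_core(psi.data(), n, L, wwin, zc, p, sig);
    double phi = ev.E + lam * ev.g + 0.5 * mu * ev.g * ev.g;
    if (vfix > 0.0 && ev.feasible) {
      double gv = ev.Vtot - vfix;
      phi += lam2 * gv + 0.5 * mu2 * gv * gv;
    }
    return phi;
  };
  for (int j = 0; j < m; ++j) {
    double save = psi[j + 1];
    psi[j + 1] = save + eps;
    double fp = phi_of();
    psi[j + 1] = save - eps;
    double fm = phi_of();
    psi[j + 1] = save;
    grad[j] = (fp - fm) / (2.0 * eps);
  }
  return grad;
}
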