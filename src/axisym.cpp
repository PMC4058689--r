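// Steady incompressible axisymmetric Navier-Stokes core in
// streamfunction-vorticity form on a radially mapped structured grid:
// xi = z, eta = r/R(z), eta in [0,1]. Mapped derivatives:
//   f_z  = f_xi - eta*a*f_eta,            a  = R'/R
//   f_r  = f_eta / R
//   f_zz = f_xixi - 2 eta a f_xieta + eta^2 a^2 f_etaeta
//          + eta (a^2 - a') f_eta,        a' = R''/R - (R'/R)^2
//   f_rr = f_etaeta / R^2
// Streamfunction:  psi_zz + psi_rr - psi_r/r = -r w   (w = azimuthal vorticity)
// Vorticity:       u_z w_z + u_r w_r - u_r w / r =
//                  nu (w_zz + w_rr + w_r/r - w/r^2)
// u_z = psi_r / r, u_r = -psi_z / r. Cross-sectional flux equals
// 2 pi (psi_wall - psi_axis) identically, so discrete mass is conserved by
// construction. Convection: first-order upwind with deferred-correction
// central scheme (weight cw). Wall vorticity by a Thom-type closure in the
// mapped metric. Axial pressure recovered by integrating the axial momentum
// equation along the axis.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List axisym_core(NumericVector z, NumericVector Rw, NumericVector Rp,
                 NumericVector Rpp, int nr, double Q, double rho, double mu,
                 double tol, int max_outer, double beta_omega,
                 double beta_wall, double sor_psi, int psi_sweeps,
                 double central_weight) {
  const int nz1 = z.size();      // xi nodes
  const int nr1 = nr + 1;        // eta nodes
  const double dxi = z[1] - z[0];
  const double deta = 1.0 / nr;
  const double nu = mu / rho;
  const double psi_w = Q / (2.0 * M_PI);
  const double cw = central_weight;

  std::vector<double> psi(nz1 * nr1), w(nz1 * nr1);
  std::vector<double> uz(nz1 * nr1, 0.0), ur(nz1 * nr1, 0.0);
  std::vector<double> eta(nr1);
  for (int j = 0; j < nr1; ++j) eta[j] = j * deta;
  auto id = [nr1](int i, int j) { return i * nr1 + j; };

  // metric coefficients per xi station
  std::vector<double> a(nz1), ap(nz1);
  for (int i = 0; i < nz1; ++i) {
    a[i] = Rp[i] / Rw[i];
    ap[i] = Rpp[i] / Rw[i] - a[i] * a[i];
  }

  // initialize with the local Poiseuille profile (exact for straight tubes)
  for (int i = 0; i < nz1; ++i) {
    for (int j = 0; j < nr1; ++j) {
      double e = eta[j];
      psi[id(i, j)] = psi_w * (2.0 * e * e - e * e * e * e);
      w[id(i, j)] = 4.0 * Q * e / (M_PI * Rw[i] * Rw[i] * Rw[i]);
    }
  }

  const double w_ref = 4.0 * Q / (M_PI * Rw[0] * Rw[0] * Rw[0]);
  double res = 1.0;
  double res_psi_last = 0, res_w_last = 0, res_wall_last = 0;
  int iter = 0;
  std::vector<double> hist;
  bool converged = false;

  for (iter = 1; iter <= max_outer; ++iter) {
    // --- streamfunction SOR sweeps ---
    double res_psi = 0.0;
    for (int sweep = 0; sweep < psi_sweeps; ++sweep) {
      res_psi = 0.0;
      for (int i = 1; i < nz1 - 1; ++i) {
        const double Aee_c = a[i] * a[i];
        const double invR2 = 1.0 / (Rw[i] * Rw[i]);
        for (int j = 1; j < nr; ++j) {
          const double e = eta[j];
          const double r = e * Rw[i];
          const double Aee = e * e * Aee_c + invR2;
          const double Be = e * (Aee_c - ap[i]) - 1.0 / (r * Rw[i]);
          const double cross = -2.0 * e * a[i];
          const double p_e = (psi[id(i, j + 1)] - psi[id(i, j - 1)]) / (2 * deta);
          const double p_xe = (psi[id(i + 1, j + 1)] - psi[id(i + 1, j - 1)]
                               - psi[id(i - 1, j + 1)] + psi[id(i - 1, j - 1)])
                              / (4 * dxi * deta);
          const double num =
            (psi[id(i + 1, j)] + psi[id(i - 1, j)]) / (dxi * dxi)
            + Aee * (psi[id(i, j + 1)] + psi[id(i, j - 1)]) / (deta * deta)
            + cross * p_xe + Be * p_e + r * w[id(i, j)];
          const double den = 2.0 / (dxi * dxi) + 2.0 * Aee / (deta * deta);
          const double pn = num / den;
          const double d = pn - psi[id(i, j)];
          if (std::fabs(d) > res_psi) res_psi = std::fabs(d);
          psi[id(i, j)] += sor_psi * d;
        }
      }
      for (int j = 0; j < nr1; ++j)               // zero-gradient outlet
        psi[id(nz1 - 1, j)] = psi[id(nz1 - 2, j)];
    }

    // --- velocities from psi ---
    for (int i = 0; i < nz1; ++i) {
      const double R2 = Rw[i] * Rw[i];
      uz[id(i, 0)] = 2.0 * psi[id(i, 1)] / (deta * deta * R2);
      ur[id(i, 0)] = 0.0;
      for (int j = 1; j < nr; ++j) {
        const double e = eta[j];
        const double p_e = (psi[id(i, j + 1)] - psi[id(i, j - 1)]) / (2 * deta);
        double p_x;
        if (i == 0) p_x = 0.0;                    // prescribed parabolic inflow
        else if (i == nz1 - 1)
          p_x = (psi[id(i, j)] - psi[id(i - 1, j)]) / dxi;
        else
          p_x = (psi[id(i + 1, j)] - psi[id(i - 1, j)]) / (2 * dxi);
        uz[id(i, j)] = p_e / (e * R2);
        ur[id(i, j)] = -(p_x - e * a[i] * p_e) / (e * Rw[i]);
      }
      uz[id(i, nr)] = 0.0;                        // no-slip wall
      ur[id(i, nr)] = 0.0;
    }

    // --- vorticity interior update (Gauss-Seidel, upwind + deferred) ---
    double res_w = 0.0;
    for (int i = 1; i < nz1 - 1; ++i) {
      const double Aee_c = a[i] * a[i];
      const double invR2 = 1.0 / (Rw[i] * Rw[i]);
      for (int j = 1; j < nr; ++j) {
        const double e = eta[j];
        const double r = e * Rw[i];
        const double Aee = e * e * Aee_c + invR2;
        const double Be = e * (Aee_c - ap[i]) + 1.0 / (r * Rw[i]);
        const double cross = -2.0 * e * a[i];
        const double U = uz[id(i, j)];
        const double V = -U * e * a[i] + ur[id(i, j)] / Rw[i];
        const double Up = U > 0 ? U : 0, Um = U < 0 ? U : 0;
        const double Vp = V > 0 ? V : 0, Vm = V < 0 ? V : 0;
        const double w_e = (w[id(i, j + 1)] - w[id(i, j - 1)]) / (2 * deta);
        const double w_x = (w[id(i + 1, j)] - w[id(i - 1, j)]) / (2 * dxi);
        const double w_xe = (w[id(i + 1, j + 1)] - w[id(i + 1, j - 1)]
                             - w[id(i - 1, j + 1)] + w[id(i - 1, j - 1)])
                            / (4 * dxi * deta);
        // deferred correction: central minus upwind at current values
        const double conv_up =
          Up * (w[id(i, j)] - w[id(i - 1, j)]) / dxi
          + Um * (w[id(i + 1, j)] - w[id(i, j)]) / dxi
          + Vp * (w[id(i, j)] - w[id(i, j - 1)]) / deta
          + Vm * (w[id(i, j + 1)] - w[id(i, j)]) / deta;
        const double conv_cd = U * w_x + V * w_e;
        double num =
          nu * ((w[id(i + 1, j)] + w[id(i - 1, j)]) / (dxi * dxi)
                + Aee * (w[id(i, j + 1)] + w[id(i, j - 1)]) / (deta * deta)
                + cross * w_xe + Be * w_e)
          + Up * w[id(i - 1, j)] / dxi - Um * w[id(i + 1, j)] / dxi
          + Vp * w[id(i, j - 1)] / deta - Vm * w[id(i, j + 1)] / deta
          - cw * (conv_cd - conv_up);
        double den = nu * (2.0 / (dxi * dxi) + 2.0 * Aee / (deta * deta)
                           + 1.0 / (r * r))
                     + (Up - Um) / dxi + (Vp - Vm) / deta;
        const double urr = ur[id(i, j)] / r;      // vortex-stretching term
        if (urr <= 0) den -= urr; else num += urr * w[id(i, j)];
        const double wn = num / den;
        const double d = wn - w[id(i, j)];
        if (std::fabs(d) > res_w) res_w = std::fabs(d);
        w[id(i, j)] += beta_omega * d;
      }
      w[id(i, 0)] = 0.0;                          // axis
    }

    // --- wall vorticity (second-order Jensen closure, mapped metric) ---
    double res_wall = 0.0;
    for (int i = 1; i < nz1; ++i) {
      const double psiee = (8.0 * psi[id(i, nr - 1)] - psi[id(i, nr - 2)]
                            - 7.0 * psi_w) / (2.0 * deta * deta);
      const double wn = -(1.0 + Rp[i] * Rp[i]) * psiee
                        / (Rw[i] * Rw[i] * Rw[i]);
      const double d = wn - w[id(i, nr)];
      if (std::fabs(d) > res_wall) res_wall = std::fabs(d);
      w[id(i, nr)] += beta_wall * d;
    }
    for (int j = 0; j < nr; ++j)                  // zero-gradient outlet
      w[id(nz1 - 1, j)] = w[id(nz1 - 2, j)];      // (wall node: Jensen closure)

    res_psi_last = res_psi; res_w_last = res_w; res_wall_last = res_wall;
    res = std::max(res_psi / psi_w,
                   std::max(res_w, res_wall) / w_ref);
    if (iter % 25 == 0 || iter == 1) hist.push_back(res);
    if (res < tol) { converged = true; break; }
  }

  // --- axial pressure: on r = 0, mu lap(u_z) = -2 mu dw/dr (vorticity is
  // odd in r), so dp/dz = -2 mu w(dr)/dr - rho u du/dz ---
  std::vector<double> u0(nz1), dpdz(nz1), p_axis(nz1);
  for (int i = 0; i < nz1; ++i) u0[i] = uz[id(i, 0)];
  for (int i = 0; i < nz1; ++i) {
    const int im = i > 0 ? i - 1 : 0, ipp = i < nz1 - 1 ? i + 1 : nz1 - 1;
    const double dz2 = (ipp - im) * dxi;
    const double du = (u0[ipp] - u0[im]) / dz2;
    // second-order one-sided estimate of dw/dr at the axis (w(0) = 0)
    const double dr = deta * Rw[i];
    const double wr = (4.0 * w[id(i, 1)] - w[id(i, 2)]) / (2.0 * dr);
    dpdz[i] = -2.0 * mu * wr - rho * u0[i] * du;
  }
  p_axis[nz1 - 1] = 0.0;
  for (int i = nz1 - 2; i >= 0; --i)
    p_axis[i] = p_axis[i + 1] - 0.5 * (dpdz[i] + dpdz[i + 1]) * dxi;

  NumericVector wall_shear(nz1);
  for (int i = 0; i < nz1; ++i) wall_shear[i] = mu * w[id(i, nr)];

  NumericMatrix psi_m(nz1, nr1), w_m(nz1, nr1), uz_m(nz1, nr1),
      ur_m(nz1, nr1);
  for (int i = 0; i < nz1; ++i)
    for (int j = 0; j < nr1; ++j) {
      psi_m(i, j) = psi[id(i, j)];
      w_m(i, j) = w[id(i, j)];
      uz_m(i, j) = uz[id(i, j)];
      ur_m(i, j) = ur[id(i, j)];
    }

  return List::create(
      _["psi"] = psi_m, _["omega"] = w_m, _["uz"] = uz_m, _["ur"] = ur_m,
      _["p_axis"] = NumericVector(p_axis.begin(), p_axis.end()),
      _["wall_shear"] = wall_shear,
      _["dp"] = p_axis[0] - p_axis[nz1 - 1],
      _["converged"] = converged, _["iterations"] = std::min(iter, max_outer),
      _["residual"] = res, _["res_psi"] = res_psi_last / psi_w,
      _["res_w"] = res_w_last / w_ref, _["res_wall"] = res_wall_last / w_ref,
      _["residual_history"] = NumericVector(hist.begin(), hist.end()));
}
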