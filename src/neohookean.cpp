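// Energy and gradient of a neo-Hookean tetrahedral body under a dead
// external load with penalty contact against a pair of rigid rounded
// diamond pillars.  Units: micrometres and pascals, so energies are in
// Pa*um^3 (fJ*1e-3) and nodal forces in pN (Pa*um^2).
//
// Strain energy density: W = C10 * (J^{-2/3} I1 - 3)
//                             + kvol * ((J^2 - 1)/2 - ln J),
// with kvol = 1/D1.  The volumetric function is the log-regularised form:
// it matches the quadratic (J - 1)^2 penalty to second order at J = 1
// (same bulk modulus) but diverges as J -> 0, which keeps crushed elements
// from collapsing under hard contact.  The contact penalty acts on surface nodes through the
// exact signed distance of the rounded pillar cross-section (distance to an
// inset rhombus minus the fillet radius); pillars span the full height, so
// the distance is two-dimensional.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Sdf2 {
  double sd;      // signed distance (negative inside)
  double gx, gy;  // gradient (unit) in world frame
};

// signed distance to the rounded rhombus pillar centred at (0, +-ceny)
inline Sdf2 pillar_sdf_pt(double px, double py, double a, double b,
                          double rf, double ceny) {
  Sdf2 out;
  const double s_pillar = (py >= 0.0) ? 1.0 : -1.0;
  double ly = std::fabs(py) - ceny;           // local y of nearer pillar
  const double s2 = (ly >= 0.0) ? 1.0 : -1.0;
  const double s1 = (px >= 0.0) ? 1.0 : -1.0;
  double qx = std::fabs(px);
  double qy = std::fabs(ly);
  // closest point on segment (a,0)-(0,b)
  const double dx = -a, dy = b;
  double t = ((qx - a) * dx + qy * dy) / (dx * dx + dy * dy);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  const double cx = a + t * dx;
  const double cy = t * dy;
  double vx = qx - cx, vy = qy - cy;
  double dist = std::sqrt(vx * vx + vy * vy);
  const bool inside = (qx / a + qy / b) < 1.0;
  double gqx, gqy;
  if (dist > 1e-12) {
    gqx = vx / dist;
    gqy = vy / dist;
    if (inside) { gqx = -gqx; gqy = -gqy; }
  } else {
    const double nn = std::sqrt(b * b + a * a);
    gqx = b / nn;
    gqy = a / nn;
  }
  out.sd = (inside ? -dist : dist) - rf;
  out.gx = gqx * s1;
  out.gy = gqy * s2 * s_pillar;
  return out;
}

} // namespace

// [[Rcpp::export]]
List nh_energy_grad(NumericVector x, IntegerMatrix tets, NumericMatrix dminv,
                    NumericVector vol0, double c10, double kvol,
                    NumericVector fext, IntegerVector snodes,
                    NumericVector sweights, double ain, double bin,
                    double rf, double ceny, double kpen) {
  const int ntet = tets.nrow();
  const int ndof = x.size();
  NumericVector grad(ndof);
  double energy = 0.0;
  double minJ = R_PosInf;
  double maxpen = 0.0;

  for (int e = 0; e < ntet; ++e) {
    const int n0 = (tets(e, 0) - 1) * 3;
    const int n1 = (tets(e, 1) - 1) * 3;
    const int n2 = (tets(e, 2) - 1) * 3;
    const int n3 = (tets(e, 3) - 1) * 3;
    double Ds[9]; // column-major edge vectors
    Ds[0] = x[n1 + 0] - x[n0 + 0];
    Ds[1] = x[n1 + 1] - x[n0 + 1];
    Ds[2] = x[n1 + 2] - x[n0 + 2];
    Ds[3] = x[n2 + 0] - x[n0 + 0];
    Ds[4] = x[n2 + 1] - x[n0 + 1];
    Ds[5] = x[n2 + 2] - x[n0 + 2];
    Ds[6] = x[n3 + 0] - x[n0 + 0];
    Ds[7] = x[n3 + 1] - x[n0 + 1];
    Ds[8] = x[n3 + 2] - x[n0 + 2];
    const double *Mi = &dminv(0, e); // 3x3 column-major
    double F[9];
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i)
        F[i + 3 * j] = Ds[i + 0] * Mi[0 + 3 * j] +
                       Ds[i + 3] * Mi[1 + 3 * j] +
                       Ds[i + 6] * Mi[2 + 3 * j];
    const double J =
        F[0] * (F[4] * F[8] - F[5] * F[7]) -
        F[3] * (F[1] * F[8] - F[2] * F[7]) +
        F[6] * (F[1] * F[5] - F[2] * F[4]);
    if (J < minJ) minJ = J;
    double I1 = 0.0;
    for (int k = 0; k < 9; ++k) I1 += F[k] * F[k];
    const double V = vol0[e];

    // Deviatoric factor g1(J) = J^{-2/3} and volumetric function
    // v(J) = (J^2 - 1)/2 - ln J, both replaced below J0 by their
    // second-order Taylor extensions (invertible-element treatment): the
    // energy stays finite and C2 for any J, including inverted elements,
    // which keeps the line search alive in deeply crushed states while the
    // extended branch still pushes strongly back toward J > J0.
    const double J0 = 0.05;
    double g1, dg1, v, dv;
    if (J >= J0) {
      g1 = std::pow(J, -2.0 / 3.0);
      dg1 = (-2.0 / 3.0) * std::pow(J, -5.0 / 3.0);
      v = 0.5 * (J * J - 1.0) - std::log(J);
      dv = J - 1.0 / J;
    } else {
      const double t = J - J0;
      const double g10 = std::pow(J0, -2.0 / 3.0);
      const double dg10 = (-2.0 / 3.0) * std::pow(J0, -5.0 / 3.0);
      const double ddg10 = (10.0 / 9.0) * std::pow(J0, -8.0 / 3.0);
      g1 = g10 + dg10 * t + 0.5 * ddg10 * t * t;
      dg1 = dg10 + ddg10 * t;
      const double v0 = 0.5 * (J0 * J0 - 1.0) - std::log(J0);
      const double dv0 = J0 - 1.0 / J0;
      const double ddv0 = 1.0 + 1.0 / (J0 * J0);
      v = v0 + dv0 * t + 0.5 * ddv0 * t * t;
      dv = dv0 + ddv0 * t;
    }
    energy += V * (c10 * (g1 * I1 - 3.0) + kvol * v);

    // cof(F): polynomial in F, finite for any J (cof_ij = d(det F)/dF_ij)
    double cof[9];
    cof[0] = F[4] * F[8] - F[7] * F[5];
    cof[1] = F[6] * F[5] - F[3] * F[8];
    cof[2] = F[3] * F[7] - F[6] * F[4];
    cof[3] = F[7] * F[2] - F[1] * F[8];
    cof[4] = F[0] * F[8] - F[6] * F[2];
    cof[5] = F[6] * F[1] - F[0] * F[7];
    cof[6] = F[1] * F[5] - F[4] * F[2];
    cof[7] = F[3] * F[2] - F[0] * F[5];
    cof[8] = F[0] * F[4] - F[3] * F[1];

    // dW/dF = 2 c10 g1 F + (c10 I1 g1' + kvol v') cof(F)
    const double cdev = 2.0 * c10 * g1;
    const double ccof = c10 * I1 * dg1 + kvol * dv;
    double P[9];
    for (int k = 0; k < 9; ++k)
      P[k] = cdev * F[k] + ccof * cof[k];

    // H = V * P * DmInv^T : column j is gradient wrt node j+1
    double H[9];
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i)
        H[i + 3 * j] = V * (P[i + 0] * Mi[j + 0] +
                            P[i + 3] * Mi[j + 3] +
                            P[i + 6] * Mi[j + 6]);
    for (int i = 0; i < 3; ++i) {
      grad[n1 + i] += H[i + 0];
      grad[n2 + i] += H[i + 3];
      grad[n3 + i] += H[i + 6];
      grad[n0 + i] -= H[i + 0] + H[i + 3] + H[i + 6];
    }
  }

  // dead external load
  for (int i = 0; i < ndof; ++i) {
    energy -= fext[i] * x[i];
    grad[i] -= fext[i];
  }

  // contact penalty on surface nodes
  if (kpen > 0.0) {
    const int ns = snodes.size();
    for (int s = 0; s < ns; ++s) {
      const int n = (snodes[s] - 1) * 3;
      Sdf2 d = pillar_sdf_pt(x[n + 0], x[n + 1], ain, bin, rf, ceny);
      if (d.sd < 0.0) {
        const double pen = -d.sd;
        const double kw = kpen * sweights[s];
        energy += 0.5 * kw * pen * pen;
        // dE/dq = kw * pen * d(pen)/dq = -kw * pen * grad(sd)
        grad[n + 0] -= kw * pen * d.gx;
        grad[n + 1] -= kw * pen * d.gy;
        if (pen > maxpen) maxpen = pen;
      }
    }
  }

  return List::create(_["energy"] = energy, _["grad"] = grad,
                      _["min_j"] = minJ, _["max_pen"] = maxpen);
}

// Deformation gradients of all tets (9 x ntet, column-major per tet),
// for post-processing stretches and volume ratios.
// [[Rcpp::export]]
NumericMatrix nh_def_grads(NumericVector x, IntegerMatrix tets,
                           NumericMatrix dminv) {
  const int ntet = tets.nrow();
  NumericMatrix out(9, ntet);
  for (int e = 0; e < ntet; ++e) {
    const int n0 = (tets(e, 0) - 1) * 3;
    const int n1 = (tets(e, 1) - 1) * 3;
    const int n2 = (tets(e, 2) - 1) * 3;
    const int n3 = (tets(e, 3) - 1) * 3;
    double Ds[9];
    Ds[0] = x[n1 + 0] - x[n0 + 0]; Ds[1] = x[n1 + 1] - x[n0 + 1];
    Ds[2] = x[n1 + 2] - x[n0 + 2];
    Ds[3] = x[n2 + 0] - x[n0 + 0]; Ds[4] = x[n2 + 1] - x[n0 + 1];
    Ds[5] = x[n2 + 2] - x[n0 + 2];
    Ds[6] = x[n3 + 0] - x[n0 + 0]; Ds[7] = x[n3 + 1] - x[n0 + 1];
    Ds[8] = x[n3 + 2] - x[n0 + 2];
    const double *Mi = &dminv(0, e);
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i)
        out(i + 3 * j, e) = Ds[i + 0] * Mi[0 + 3 * j] +
                            Ds[i + 3] * Mi[1 + 3 * j] +
                            Ds[i + 6] * Mi[2 + 3 * j];
  }
  return out;
}

// Maximum contact penetration of surface nodes (no energy), for reporting.
// [[Rcpp::export]]
double nh_max_penetration(NumericVector x, IntegerVector snodes, double ain,
                          double bin, double rf, double ceny) {
  double maxpen = 0.0;
  for (int s = 0; s < snodes.size(); ++s) {
    const int n = (snodes[s] - 1) * 3;
    Sdf2 d = pillar_sdf_pt(x[n + 0], x[n + 1], ain, bin, rf, ceny);
    if (-d.sd > maxpen) maxpen = -d.sd;
  }
  return maxpen;
}
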