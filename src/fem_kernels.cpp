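// tet4 element kernels: internal forces, strain energies, Cauchy stresses
// and finite-difference consistent tangents for linear-elastic and
// compressible Mooney-Rivlin materials.  Units: mm, N, MPa.
//
// Element convention: reference edge matrix Dm = [X2-X1, X3-X1, X4-X1],
// Bm = Dm^-1, F = I + dU * Bm with dU = [u2-u1, u3-u1, u4-u1].
// Linear elements use small-strain kinematics (eps = sym(dU * Bm)), so the
// patch test is exact; hyperelastic elements are total-Lagrangian.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

typedef double M3[3][3];

static inline double det3(const M3 a) {
  return a[0][0] * (a[1][1] * a[2][2] - a[1][2] * a[2][1]) -
         a[0][1] * (a[1][0] * a[2][2] - a[1][2] * a[2][0]) +
         a[0][2] * (a[1][0] * a[2][1] - a[1][1] * a[2][0]);
}

static inline bool inv3(const M3 a, M3 out) {
  double d = det3(a);
  if (d == 0.0) return false;
  double id = 1.0 / d;
  out[0][0] =  (a[1][1] * a[2][2] - a[1][2] * a[2][1]) * id;
  out[0][1] = -(a[0][1] * a[2][2] - a[0][2] * a[2][1]) * id;
  out[0][2] =  (a[0][1] * a[1][2] - a[0][2] * a[1][1]) * id;
  out[1][0] = -(a[1][0] * a[2][2] - a[1][2] * a[2][0]) * id;
  out[1][1] =  (a[0][0] * a[2][2] - a[0][2] * a[2][0]) * id;
  out[1][2] = -(a[0][0] * a[1][2] - a[0][2] * a[1][0]) * id;
  out[2][0] =  (a[1][0] * a[2][1] - a[1][1] * a[2][0]) * id;
  out[2][1] = -(a[0][0] * a[2][1] - a[0][1] * a[2][0]) * id;
  out[2][2] =  (a[0][0] * a[1][1] - a[0][1] * a[1][0]) * id;
  return true;
}

static inline void matmul(const M3 a, const M3 b, M3 out) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += a[i][k] * b[k][j];
      out[i][j] = s;
    }
}

// P and W for compressible Mooney-Rivlin; returns false on inversion.
static bool mr_pk1_w(const M3 F, double C1, double C2, double K,
                     M3 P, double *W) {
  double J = det3(F);
  if (J <= 0.0) return false;
  M3 Ft, C, FC, Finv, Finvt;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Ft[i][j] = F[j][i];
  matmul(Ft, (const double(*)[3])F, C);
  double I1 = C[0][0] + C[1][1] + C[2][2];
  double CC = 0.0;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) CC += C[i][j] * C[i][j];
  double I2 = 0.5 * (I1 * I1 - CC);
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double Jm43 = Jm23 * Jm23;
  double I1b = Jm23 * I1, I2b = Jm43 * I2;
  if (!inv3((const double(*)[3])F, Finv)) return false;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Finvt[i][j] = Finv[j][i];
  matmul((const double(*)[3])F, (const double(*)[3])C, FC);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double dI1 = 2.0 * F[i][j];
      double dI2 = 2.0 * (I1 * F[i][j] - FC[i][j]);
      double dJ = J * Finvt[i][j];
      double dI1b = Jm23 * dI1 - (2.0 / 3.0) * I1b / J * dJ;
      double dI2b = Jm43 * dI2 - (4.0 / 3.0) * I2b / J * dJ;
      P[i][j] = C1 * dI1b + C2 * dI2b + K * (J - 1.0) * dJ;
    }
  if (W) *W = C1 * (I1b - 3.0) + C2 * (I2b - 3.0) + 0.5 * K * (J - 1.0) * (J - 1.0);
  return true;
}

// Element internal force (12-vector) and energy.  matcode 0: linear
// (par0 = lambda, par1 = mu); 1: Mooney-Rivlin (par0..2 = C1, C2, K).
// Returns false on element inversion (hyperelastic only).
static bool elem_force(const double Xe[4][3], const double ue[12],
                       const M3 Bm, double vol, int matcode,
                       const double *par, double fe[12], double *W) {
  M3 dU, H, P;
  for (int c = 0; c < 3; ++c)
    for (int i = 0; i < 3; ++i)
      dU[i][c] = ue[3 * (c + 1) + i] - ue[i];
  matmul((const double(*)[3])dU, Bm, H);
  if (matcode == 0) {
    double lam = par[0], mu = par[1];
    M3 eps, sig;
    double tr = 0.0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) eps[i][j] = 0.5 * (H[i][j] + H[j][i]);
    tr = eps[0][0] + eps[1][1] + eps[2][2];
    double e2 = 0.0;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        sig[i][j] = 2.0 * mu * eps[i][j] + (i == j ? lam * tr : 0.0);
        e2 += eps[i][j] * eps[i][j];
      }
    if (W) *W = vol * (0.5 * lam * tr * tr + mu * e2);
    for (int i = 0; i < 3; ++i) P[0][i] = sig[0][i];
    for (int i = 0; i < 3; ++i) P[1][i] = sig[1][i];
    for (int i = 0; i < 3; ++i) P[2][i] = sig[2][i];
  } else {
    M3 F;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) F[i][j] = H[i][j] + (i == j ? 1.0 : 0.0);
    double w;
    if (!mr_pk1_w((const double(*)[3])F, par[0], par[1], par[2], P, &w))
      return false;
    if (W) *W = vol * w;
  }
  // G = vol * P * Bm^T; columns are forces on nodes 2..4
  for (int c = 0; c < 3; ++c) {
    for (int i = 0; i < 3; ++i) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += P[i][k] * Bm[c][k];
      fe[3 * (c + 1) + i] = vol * s;
    }
  }
  for (int i = 0; i < 3; ++i)
    fe[i] = -(fe[3 + i] + fe[6 + i] + fe[9 + i]);
  return true;
}

static void gather(const NumericMatrix &nodes, const IntegerMatrix &tets,
                   const NumericVector &u, int e, double Xe[4][3],
                   double ue[12], int dof[12]) {
  for (int a = 0; a < 4; ++a) {
    int n = tets(e, a) - 1;
    for (int i = 0; i < 3; ++i) {
      Xe[a][i] = nodes(n, i);
      ue[3 * a + i] = u[3 * n + i];
      dof[3 * a + i] = 3 * n + i;
    }
  }
}

static bool elem_setup(const double Xe[4][3], M3 Bm, double *vol) {
  M3 Dm;
  for (int c = 0; c < 3; ++c)
    for (int i = 0; i < 3; ++i) Dm[i][c] = Xe[c + 1][i] - Xe[0][i];
  double d = det3((const double(*)[3])Dm);
  if (d <= 0.0) return false;
  *vol = d / 6.0;
  return inv3((const double(*)[3])Dm, Bm);
}

// [[Rcpp::export(name = ".tet4_assemble_cpp")]]
List tet4_assemble_cpp(NumericMatrix nodes, IntegerMatrix tets,
                       NumericVector u, IntegerVector matcode,
                       NumericMatrix matpar, bool want_tangent,
                       double fd_rel) {
  int nel = tets.nrow(), nn = nodes.nrow();
  NumericVector f(3 * nn);
  NumericVector energy(nel);
  int inverted = 0;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_tangent) {
    ti.reserve((size_t)nel * 144);
    tj.reserve((size_t)nel * 144);
    tx.reserve((size_t)nel * 144);
  }
  for (int e = 0; e < nel; ++e) {
    double Xe[4][3], ue[12], fe[12], W;
    int dof[12];
    M3 Bm;
    double vol;
    gather(nodes, tets, u, e, Xe, ue, dof);
    if (!elem_setup(Xe, Bm, &vol)) { inverted = e + 1; break; }
    double parv[3];
    int row = (matcode.size() == 1) ? 0 : e;
    for (int k = 0; k < 3; ++k) parv[k] = matpar(row, k);
    int mc = matcode[row];
    if (!elem_force(Xe, ue, (const double(*)[3])Bm, vol, mc, parv, fe, &W)) {
      inverted = e + 1; break;
    }
    energy[e] = W;
    for (int i = 0; i < 12; ++i) f[dof[i]] += fe[i];
    if (want_tangent) {
      double h = fd_rel * std::cbrt(6.0 * vol);
      double Ke[12][12];
      double up[12], fp[12], fm[12];
      bool ok = true;
      for (int j = 0; j < 12 && ok; ++j) {
        for (int i = 0; i < 12; ++i) up[i] = ue[i];
        up[j] = ue[j] + h;
        ok = elem_force(Xe, up, (const double(*)[3])Bm, vol, mc, parv, fp, 0);
        up[j] = ue[j] - h;
        ok = ok && elem_force(Xe, up, (const double(*)[3])Bm, vol, mc, parv, fm, 0);
        if (ok)
          for (int i = 0; i < 12; ++i) Ke[i][j] = (fp[i] - fm[i]) / (2.0 * h);
      }
      if (!ok) { inverted = e + 1; break; }
      for (int i = 0; i < 12; ++i)
        for (int j = 0; j < 12; ++j) {
          double v = 0.5 * (Ke[i][j] + Ke[j][i]);   // symmetrize
          ti.push_back(dof[i] + 1);
          tj.push_back(dof[j] + 1);
          tx.push_back(v);
        }
    }
  }
  return List::create(_["f"] = f, _["energy"] = energy,
                      _["inverted"] = inverted,
                      _["ti"] = wrap(ti), _["tj"] = wrap(tj),
                      _["tx"] = wrap(tx));
}

// Per-element Cauchy stress in Voigt order (xx, yy, zz, xy, yz, xz).
// [[Rcpp::export(name = ".tet4_stress_cpp")]]
NumericMatrix tet4_stress_cpp(NumericMatrix nodes, IntegerMatrix tets,
                              NumericVector u, IntegerVector matcode,
                              NumericMatrix matpar) {
  int nel = tets.nrow();
  NumericMatrix out(nel, 6);
  for (int e = 0; e < nel; ++e) {
    double Xe[4][3], ue[12];
    int dof[12];
    M3 Bm, dU, H;
    double vol;
    gather(nodes, tets, u, e, Xe, ue, dof);
    if (!elem_setup(Xe, Bm, &vol)) stop("degenerate element %d", e + 1);
    for (int c = 0; c < 3; ++c)
      for (int i = 0; i < 3; ++i)
        dU[i][c] = ue[3 * (c + 1) + i] - ue[i];
    matmul((const double(*)[3])dU, (const double(*)[3])Bm, H);
    double parv[3];
    int row = (matcode.size() == 1) ? 0 : e;
    for (int k = 0; k < 3; ++k) parv[k] = matpar(row, k);
    int mc = matcode[row];
    M3 sig;
    if (mc == 0) {
      double lam = parv[0], mu = parv[1];
      double tr = H[0][0] + H[1][1] + H[2][2];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          sig[i][j] = mu * (H[i][j] + H[j][i]) + (i == j ? lam * tr : 0.0);
    } else {
      M3 F, P, Ft, PFt;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) F[i][j] = H[i][j] + (i == j ? 1.0 : 0.0);
      if (!mr_pk1_w((const double(*)[3])F, parv[0], parv[1], parv[2], P, 0))
        stop("element inversion in stress recovery at element %d", e + 1);
      double J = det3((const double(*)[3])F);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) Ft[i][j] = F[j][i];
      matmul((const double(*)[3])P, (const double(*)[3])Ft, PFt);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          sig[i][j] = 0.5 * (PFt[i][j] + PFt[j][i]) / J;
    }
    out(e, 0) = sig[0][0]; out(e, 1) = sig[1][1]; out(e, 2) = sig[2][2];
    out(e, 3) = sig[0][1]; out(e, 4) = sig[1][2]; out(e, 5) = sig[0][2];
  }
  return out;
}
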