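#ifndef CILIAFLOW_FIBER_H
#define CILIAFLOW_FIBER_H

#include "core.h"

// Node-spring fiber forces. X,Y are node coordinate arrays of length n.
// closed = periodic chain with x-offset Lx on the seam segment (membrane);
// open fibers (cilia) have free ends.
//
// Stretching: segment tension T_j = ks (|dX_j|/ds - 1), nodal force the
// discrete divergence of T t-hat (telescopes to zero net force).
inline void stretch_force_core(const double* X, const double* Y, int n,
                               double ks, double ds, bool closed, double Lx,
                               double* FX, double* FY) {
  int nseg = closed ? n : n - 1;
  for (int k = 0; k < n; ++k) { FX[k] = 0.0; FY[k] = 0.0; }
  for (int j = 0; j < nseg; ++j) {
    int a = j, b = (j + 1) % n;
    double dx = X[b] - X[a] + ((closed && b == 0) ? Lx : 0.0);
    double dy = Y[b] - Y[a];
    double len = std::sqrt(dx * dx + dy * dy);
    if (len < 1e-12) Rcpp::stop("fiber: coincident adjacent nodes");
    double T = ks * (len / ds - 1.0) / ds; // force density along s
    double tx = dx / len, ty = dy / len;
    FX[a] += T * tx; FY[a] += T * ty;
    FX[b] -= T * tx; FY[b] -= T * ty;
  }
}

// Bending: variational derivative of E_b = (kb/2) sum_j |D2 X_j|^2 / ds^3,
// F = -kb D2(D2 X) with D2 zero outside the interior for open fibers. The
// natural boundary conditions of this form are the free-end moment/shear
// conditions; net force and torque vanish identically.
inline void bend_force_core(const double* X, const double* Y, int n,
                            double kb, double ds, bool closed, double Lx,
                            double* FX, double* FY) {
  std::vector<double> CX(n, 0.0), CY(n, 0.0);
  double inv4 = kb / (ds * ds * ds * ds);
  if (closed) {
    for (int j = 0; j < n; ++j) {
      int jm = (j - 1 + n) % n, jp = (j + 1) % n;
      double ox_m = (j == 0) ? -Lx : 0.0;
      double ox_p = (jp == 0) ? Lx : 0.0;
      CX[j] = X[jm] + ox_m - 2.0 * X[j] + X[jp] + ox_p;
      CY[j] = Y[jm] - 2.0 * Y[j] + Y[jp];
    }
    for (int j = 0; j < n; ++j) {
      int jm = (j - 1 + n) % n, jp = (j + 1) % n;
      FX[j] = -inv4 * (CX[jm] - 2.0 * CX[j] + CX[jp]);
      FY[j] = -inv4 * (CY[jm] - 2.0 * CY[j] + CY[jp]);
    }
  } else {
    for (int j = 1; j < n - 1; ++j) {
      CX[j] = X[j - 1] - 2.0 * X[j] + X[j + 1];
      CY[j] = Y[j - 1] - 2.0 * Y[j] + Y[j + 1];
    }
    for (int j = 0; j < n; ++j) {
      double cxm = (j > 0) ? CX[j - 1] : 0.0;
      double cxp = (j < n - 1) ? CX[j + 1] : 0.0;
      double cym = (j > 0) ? CY[j - 1] : 0.0;
      double cyp = (j < n - 1) ? CY[j + 1] : 0.0;
      FX[j] = -inv4 * (cxm - 2.0 * CX[j] + cxp);
      FY[j] = -inv4 * (cym - 2.0 * CY[j] + cyp);
    }
  }
}

#endif
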