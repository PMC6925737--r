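#ifndef CILIAFLOW_IB_H
#define CILIAFLOW_IB_H

#include "core.h"

// Spread one Lagrangian point force (Fx,Fy)*ds onto the lattice force field.
// Periodic in x; the kernel is clipped at the y-walls (force falling beyond a
// wall is absorbed by it).
inline void spread_point(double X, double Y, double Fx, double Fy, double ds,
                         int kind, int nx, int ny, double* fx, double* fy) {
  int supp = (kind == 2) ? 1 : (kind == 5 ? 3 : 2);
  int i0 = (int)std::floor(X);
  int j0 = (int)std::floor(Y);
  for (int dj = -supp + 1; dj <= supp; ++dj) {
    int j = j0 + dj;
    if (j < 0 || j >= ny) continue;
    double py = ib_phi1(Y - j, kind);
    if (py == 0.0) continue;
    for (int di = -supp + 1; di <= supp; ++di) {
      int iw = wrap_i(i0 + di, nx);
      double w = ib_phi1(X - (i0 + di), kind) * py * ds;
      size_t k = iw + (size_t)nx * j;
      fx[k] += w * Fx;
      fy[k] += w * Fy;
    }
  }
}

// Interpolate lattice velocity at a Lagrangian point (periodic x, clipped y).
inline void interp_point(double X, double Y, int kind, int nx, int ny,
                         const double* ux, const double* uy,
                         double* Ux, double* Uy) {
  int supp = (kind == 2) ? 1 : (kind == 5 ? 3 : 2);
  int i0 = (int)std::floor(X);
  int j0 = (int)std::floor(Y);
  double sx = 0.0, sy = 0.0;
  for (int dj = -supp + 1; dj <= supp; ++dj) {
    int j = j0 + dj;
    if (j < 0 || j >= ny) continue;
    double py = ib_phi1(Y - j, kind);
    if (py == 0.0) continue;
    for (int di = -supp + 1; di <= supp; ++di) {
      int iw = wrap_i(i0 + di, nx);
      double w = ib_phi1(X - (i0 + di), kind) * py;
      size_t k = iw + (size_t)nx * j;
      sx += w * ux[k];
      sy += w * uy[k];
    }
  }
  *Ux = sx;
  *Uy = sy;
}

#endif
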