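#ifndef CILIAFLOW_STRESS_H
#define CILIAFLOW_STRESS_H

#include "core.h"

// Centered velocity-gradient tensor L_ab = d u_a / d x_b on the lattice.
// x wraps when xper; y uses one-sided differences at the walls (or wraps when
// yper). Output arrays Lxx, Lxy (du_x/dy), Lyx (du_y/dx), Lyy.
inline void velocity_gradient_core(const double* ux, const double* uy,
                                   int nx, int ny, bool xper, bool yper,
                                   double* Lxx, double* Lxy,
                                   double* Lyx, double* Lyy) {
  // centered interior; second-order one-sided at non-periodic edges
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t k = i + (size_t)nx * j;
      double dx_u, dx_v, dy_u, dy_v;
      if (!xper && i == 0) {
        size_t k1 = 1 + (size_t)nx * j, k2 = 2 + (size_t)nx * j;
        dx_u = 0.5 * (-3.0 * ux[k] + 4.0 * ux[k1] - ux[k2]);
        dx_v = 0.5 * (-3.0 * uy[k] + 4.0 * uy[k1] - uy[k2]);
      } else if (!xper && i == nx - 1) {
        size_t k1 = (nx - 2) + (size_t)nx * j, k2 = (nx - 3) + (size_t)nx * j;
        dx_u = 0.5 * (3.0 * ux[k] - 4.0 * ux[k1] + ux[k2]);
        dx_v = 0.5 * (3.0 * uy[k] - 4.0 * uy[k1] + uy[k2]);
      } else {
        int ip = xper ? wrap_i(i + 1, nx) : i + 1;
        int im = xper ? wrap_i(i - 1, nx) : i - 1;
        size_t kxp = ip + (size_t)nx * j, kxm = im + (size_t)nx * j;
        dx_u = 0.5 * (ux[kxp] - ux[kxm]);
        dx_v = 0.5 * (uy[kxp] - uy[kxm]);
      }
      if (!yper && j == 0) {
        size_t k1 = i + (size_t)nx * 1, k2 = i + (size_t)nx * 2;
        dy_u = 0.5 * (-3.0 * ux[k] + 4.0 * ux[k1] - ux[k2]);
        dy_v = 0.5 * (-3.0 * uy[k] + 4.0 * uy[k1] - uy[k2]);
      } else if (!yper && j == ny - 1) {
        size_t k1 = i + (size_t)nx * (ny - 2), k2 = i + (size_t)nx * (ny - 3);
        dy_u = 0.5 * (3.0 * ux[k] - 4.0 * ux[k1] + ux[k2]);
        dy_v = 0.5 * (3.0 * uy[k] - 4.0 * uy[k1] + uy[k2]);
      } else {
        int jp = yper ? wrap_i(j + 1, ny) : j + 1;
        int jm = yper ? wrap_i(j - 1, ny) : j - 1;
        size_t kyp = i + (size_t)nx * jp, kym = i + (size_t)nx * jm;
        dy_u = 0.5 * (ux[kyp] - ux[kym]);
        dy_v = 0.5 * (uy[kyp] - uy[kym]);
      }
      Lxx[k] = dx_u;
      Lyx[k] = dx_v;
      Lxy[k] = dy_u;
      Lyy[k] = dy_v;
    }
}

// One explicit step of the UCM elastic-stress transport equation
//   ds/dt = -(u.grad)s + L s + s L^T + (2 etaE D - s)/lambda
// with first-order upwind advection. etaE varies per node (zero outside the
// viscoelastic layer); symmetry holds by construction (xy component shared).
inline void stress_advance_core(double* sxx, double* sxy, double* syy,
                                const double* ux, const double* uy,
                                const double* Lxx, const double* Lxy,
                                const double* Lyx, const double* Lyy,
                                const double* etaE, double lambda, double dt,
                                int nx, int ny, bool xper,
                                double kappa = 0.0) {
  size_t nn = (size_t)nx * ny;
  static thread_local std::vector<double> nxx, nxy, nyy;
  nxx.resize(nn); nxy.resize(nn); nyy.resize(nn);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t k = i + (size_t)nx * j;
      double vx = ux[k], vy = uy[k];
      // upwind advection derivatives
      int ixm = xper ? wrap_i(i - 1, nx) : std::max(i - 1, 0);
      int ixp = xper ? wrap_i(i + 1, nx) : std::min(i + 1, nx - 1);
      int jym = std::max(j - 1, 0);
      int jyp = std::min(j + 1, ny - 1);
      size_t kxm = ixm + (size_t)nx * j, kxp = ixp + (size_t)nx * j;
      size_t kym = i + (size_t)nx * jym, kyp = i + (size_t)nx * jyp;
      double adv_xx, adv_xy, adv_yy;
      if (vx >= 0.0) {
        adv_xx = vx * (sxx[k] - sxx[kxm]);
        adv_xy = vx * (sxy[k] - sxy[kxm]);
        adv_yy = vx * (syy[k] - syy[kxm]);
      } else {
        adv_xx = vx * (sxx[kxp] - sxx[k]);
        adv_xy = vx * (sxy[kxp] - sxy[k]);
        adv_yy = vx * (syy[kxp] - syy[k]);
      }
      if (vy >= 0.0) {
        adv_xx += vy * (sxx[k] - sxx[kym]);
        adv_xy += vy * (sxy[k] - sxy[kym]);
        adv_yy += vy * (syy[k] - syy[kym]);
      } else {
        adv_xx += vy * (sxx[kyp] - sxx[k]);
        adv_xy += vy * (sxy[kyp] - sxy[k]);
        adv_yy += vy * (syy[kyp] - syy[k]);
      }
      // L s + s L^T
      double ls_xx = 2.0 * (Lxx[k] * sxx[k] + Lxy[k] * sxy[k]);
      double ls_yy = 2.0 * (Lyx[k] * sxy[k] + Lyy[k] * syy[k]);
      double ls_xy = Lxx[k] * sxy[k] + Lxy[k] * syy[k]
                   + Lyx[k] * sxx[k] + Lyy[k] * sxy[k];
      double Dxx = Lxx[k], Dyy = Lyy[k];
      double Dxy = 0.5 * (Lxy[k] + Lyx[k]);
      // optional small artificial stress diffusion (stabilizes the explicit
      // transport at high Weissenberg number; zero-flux at walls)
      double dif_xx = 0.0, dif_xy = 0.0, dif_yy = 0.0;
      if (kappa > 0.0) {
        dif_xx = kappa * (sxx[kxm] + sxx[kxp] + sxx[kym] + sxx[kyp]
                          - 4.0 * sxx[k]);
        dif_xy = kappa * (sxy[kxm] + sxy[kxp] + sxy[kym] + sxy[kyp]
                          - 4.0 * sxy[k]);
        dif_yy = kappa * (syy[kxm] + syy[kxp] + syy[kym] + syy[kyp]
                          - 4.0 * syy[k]);
      }
      nxx[k] = sxx[k] + dt * (-adv_xx + ls_xx + dif_xx
                              + (2.0 * etaE[k] * Dxx - sxx[k]) / lambda);
      nxy[k] = sxy[k] + dt * (-adv_xy + ls_xy + dif_xy
                              + (2.0 * etaE[k] * Dxy - sxy[k]) / lambda);
      nyy[k] = syy[k] + dt * (-adv_yy + ls_yy + dif_yy
                              + (2.0 * etaE[k] * Dyy - syy[k]) / lambda);
    }
  std::copy(nxx.begin(), nxx.end(), sxx);
  std::copy(nxy.begin(), nxy.end(), sxy);
  std::copy(nyy.begin(), nyy.end(), syy);
}

// Fused gradient + UCM transport step used by the engine hot loop: computes
// the velocity gradient per node on the fly (same stencils as
// velocity_gradient_core with yper = false) instead of materializing the four
// gradient fields.
inline void stress_advance_fused(double* sxx, double* sxy, double* syy,
                                 const double* ux, const double* uy,
                                 const double* etaE, double lambda, double dt,
                                 int nx, int ny, bool xper, double kappa) {
  size_t nn = (size_t)nx * ny;
  static thread_local std::vector<double> nxx, nxy, nyy;
  nxx.resize(nn); nxy.resize(nn); nyy.resize(nn);
  for (int j = 0; j < ny; ++j) {
    int jym = std::max(j - 1, 0), jyp = std::min(j + 1, ny - 1);
    for (int i = 0; i < nx; ++i) {
      size_t k = i + (size_t)nx * j;
      double vx = ux[k], vy = uy[k];
      int ixm = xper ? (i == 0 ? nx - 1 : i - 1) : std::max(i - 1, 0);
      int ixp = xper ? (i == nx - 1 ? 0 : i + 1) : std::min(i + 1, nx - 1);
      size_t kxm = ixm + (size_t)nx * j, kxp = ixp + (size_t)nx * j;
      size_t kym = i + (size_t)nx * jym, kyp = i + (size_t)nx * jyp;
      // velocity gradient (centered; 2nd-order one-sided at walls)
      double Lxxk, Lxyk, Lyxk, Lyyk;
      if (!xper && i == 0) {
        size_t k1 = 1 + (size_t)nx * j, k2 = 2 + (size_t)nx * j;
        Lxxk = 0.5 * (-3.0 * ux[k] + 4.0 * ux[k1] - ux[k2]);
        Lyxk = 0.5 * (-3.0 * uy[k] + 4.0 * uy[k1] - uy[k2]);
      } else if (!xper && i == nx - 1) {
        size_t k1 = (nx - 2) + (size_t)nx * j, k2 = (nx - 3) + (size_t)nx * j;
        Lxxk = 0.5 * (3.0 * ux[k] - 4.0 * ux[k1] + ux[k2]);
        Lyxk = 0.5 * (3.0 * uy[k] - 4.0 * uy[k1] + uy[k2]);
      } else {
        Lxxk = 0.5 * (ux[kxp] - ux[kxm]);
        Lyxk = 0.5 * (uy[kxp] - uy[kxm]);
      }
      if (j == 0) {
        size_t k1 = i + (size_t)nx * 1, k2 = i + (size_t)nx * 2;
        Lxyk = 0.5 * (-3.0 * ux[k] + 4.0 * ux[k1] - ux[k2]);
        Lyyk = 0.5 * (-3.0 * uy[k] + 4.0 * uy[k1] - uy[k2]);
      } else if (j == ny - 1) {
        size_t k1 = i + (size_t)nx * (ny - 2), k2 = i + (size_t)nx * (ny - 3);
        Lxyk = 0.5 * (3.0 * ux[k] - 4.0 * ux[k1] + ux[k2]);
        Lyyk = 0.5 * (3.0 * uy[k] - 4.0 * uy[k1] + uy[k2]);
      } else {
        Lxyk = 0.5 * (ux[kyp] - ux[kym]);
        Lyyk = 0.5 * (uy[kyp] - uy[kym]);
      }
      double adv_xx, adv_xy, adv_yy;
      if (vx >= 0.0) {
        adv_xx = vx * (sxx[k] - sxx[kxm]);
        adv_xy = vx * (sxy[k] - sxy[kxm]);
        adv_yy = vx * (syy[k] - syy[kxm]);
      } else {
        adv_xx = vx * (sxx[kxp] - sxx[k]);
        adv_xy = vx * (sxy[kxp] - sxy[k]);
        adv_yy = vx * (syy[kxp] - syy[k]);
      }
      if (vy >= 0.0) {
        adv_xx += vy * (sxx[k] - sxx[kym]);
        adv_xy += vy * (sxy[k] - sxy[kym]);
        adv_yy += vy * (syy[k] - syy[kym]);
      } else {
        adv_xx += vy * (sxx[kyp] - sxx[k]);
        adv_xy += vy * (sxy[kyp] - sxy[k]);
        adv_yy += vy * (syy[kyp] - syy[k]);
      }
      double ls_xx = 2.0 * (Lxxk * sxx[k] + Lxyk * sxy[k]);
      double ls_yy = 2.0 * (Lyxk * sxy[k] + Lyyk * syy[k]);
      double ls_xy = Lxxk * sxy[k] + Lxyk * syy[k]
                   + Lyxk * sxx[k] + Lyyk * sxy[k];
      double Dxy = 0.5 * (Lxyk + Lyxk);
      double dif_xx = 0.0, dif_xy = 0.0, dif_yy = 0.0;
      if (kappa > 0.0) {
        dif_xx = kappa * (sxx[kxm] + sxx[kxp] + sxx[kym] + sxx[kyp]
                          - 4.0 * sxx[k]);
        dif_xy = kappa * (sxy[kxm] + sxy[kxp] + sxy[kym] + sxy[kyp]
                          - 4.0 * sxy[k]);
        dif_yy = kappa * (syy[kxm] + syy[kxp] + syy[kym] + syy[kyp]
                          - 4.0 * syy[k]);
      }
      double il = 1.0 / lambda;
      nxx[k] = sxx[k] + dt * (-adv_xx + ls_xx + dif_xx
                              + (2.0 * etaE[k] * Lxxk - sxx[k]) * il);
      nxy[k] = sxy[k] + dt * (-adv_xy + ls_xy + dif_xy
                              + (2.0 * etaE[k] * Dxy - sxy[k]) * il);
      nyy[k] = syy[k] + dt * (-adv_yy + ls_yy + dif_yy
                              + (2.0 * etaE[k] * Lyyk - syy[k]) * il);
    }
  }
  std::copy(nxx.begin(), nxx.end(), sxx);
  std::copy(nxy.begin(), nxy.end(), sxy);
  std::copy(nyy.begin(), nyy.end(), syy);
}

// Body-force density f = div(ind * sigma_E), centered differences, periodic x
// optional, one-sided at y-walls. Tapers to zero where ind = 0.
inline void stress_divergence_core(const double* sxx, const double* sxy,
                                   const double* syy, const double* ind,
                                   int nx, int ny, bool xper,
                                   double* fx, double* fy) {
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t k = i + (size_t)nx * j;
      int ip = i + 1, im = i - 1;
      double ddx = 0.5;
      if (xper) { ip = wrap_i(ip, nx); im = wrap_i(im, nx); }
      else if (i == 0) { im = 0; ddx = 1.0; }
      else if (i == nx - 1) { ip = nx - 1; ddx = 1.0; }
      int jp = j + 1, jm = j - 1;
      double ddy = 0.5;
      if (j == 0) { jm = 0; ddy = 1.0; }
      else if (j == ny - 1) { jp = ny - 1; ddy = 1.0; }
      size_t kxp = ip + (size_t)nx * j, kxm = im + (size_t)nx * j;
      size_t kyp = i + (size_t)nx * jp, kym = i + (size_t)nx * jm;
      fx[k] += ddx * (ind[kxp] * sxx[kxp] - ind[kxm] * sxx[kxm])
             + ddy * (ind[kyp] * sxy[kyp] - ind[kym] * sxy[kym]);
      fy[k] += ddx * (ind[kxp] * sxy[kxp] - ind[kxm] * sxy[kxm])
             + ddy * (ind[kyp] * syy[kyp] - ind[kym] * syy[kym]);
    }
}

#endif
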