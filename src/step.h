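#ifndef CILIAFLOW_STEP_H
#define CILIAFLOW_STEP_H

#include "core.h"

// Field storage: column-major (nx rows, ny cols) matrices, g is nx*ny*9 with
// q the slowest index: g[i + nx*(j + ny*q)].
#define GIDX(i, j, q) ((i) + nx * ((j) + (size_t)ny * (q)))
#define FIDX(i, j)    ((i) + nx * (j))

inline void macroscopic_core(const double* g, const double* fx,
                             const double* fy, int nx, int ny,
                             double* rho, double* ux, double* uy) {
  size_t nn = (size_t)nx * ny;
  const double *g0 = g, *g1 = g + nn, *g2 = g + 2 * nn, *g3 = g + 3 * nn,
    *g4 = g + 4 * nn, *g5 = g + 5 * nn, *g6 = g + 6 * nn, *g7 = g + 7 * nn,
    *g8 = g + 8 * nn;
  for (size_t k = 0; k < nn; ++k) {
    rho[k] = g0[k] + g1[k] + g2[k] + g3[k] + g4[k] + g5[k] + g6[k] + g7[k]
      + g8[k];
    // incompressible lattice: momentum is rho0 u with rho0 = 1;
    // Guo half-force velocity correction
    ux[k] = (g1[k] + g5[k] + g8[k]) - (g3[k] + g6[k] + g7[k]) + 0.5 * fx[k];
    uy[k] = (g2[k] + g5[k] + g6[k]) - (g4[k] + g7[k] + g8[k]) + 0.5 * fy[k];
  }
}

// BGK collision with Guo forcing into gpost, then streaming back into g.
// Unknown wall populations are closed by halfway bounce-back (no-slip) or
// specular reflection (slip). Periodic edges wrap. NEE edges are overwritten
// afterwards by nee_column()/nee_row().
inline void collide_stream_core(double* g, double* gpost, int nx, int ny,
                                const double* rho, const double* ux,
                                const double* uy, const double* fx,
                                const double* fy, const double* tau,
                                int bc_bottom, int bc_top,
                                int bc_left, int bc_right) {
  // collision (shared per-node subexpressions across the 9 directions)
  size_t plane = (size_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t k = FIDX(i, j);
      double r = rho[k], vx = ux[k], vy = uy[k];
      double t = tau[k], omega = 1.0 / t;
      double fxk = fx[k], fyk = fy[k];
      double gpref = 1.0 - 0.5 * omega;
      double u2h = 0.5 * (vx * vx + vy * vy) / CS2;
      double uf = vx * fxk + vy * fyk;
      for (int q = 0; q < 9; ++q) {
        double eu = EX[q] * vx + EY[q] * vy;
        double ef = EX[q] * fxk + EY[q] * fyk;
        double eq = WQ[q] * (r + eu / CS2 + 4.5 * eu * eu - u2h);
        double G = gpref * WQ[q] * ((ef - uf) / CS2 + 9.0 * eu * ef);
        double gq = g[k + plane * q];
        gpost[k + plane * q] = gq - omega * (gq - eq) + G;
      }
    }
  // streaming with wall closure: per (q, row), one contiguous x-shifted copy
  // from the source row (x out-of-range wraps; non-periodic x edges are
  // overwritten by the NEE columns afterwards)
  bool xper = (bc_left == BC_PERIODIC && bc_right == BC_PERIODIC);
  for (int q = 0; q < 9; ++q) {
    int ex = EX[q];
    for (int j = 0; j < ny; ++j) {
      int sj = j - EY[q];
      const double* src;
      int sq = q, shift = ex; // source index: i - shift
      if (sj < 0) {
        if (bc_bottom == BC_PERIODIC) { sj += ny; }
        else if (bc_bottom == BC_SLIP) { sj = 0; sq = MIR[q]; }
        else { sj = 0; sq = OPP[q]; shift = 0; } // halfway bounce-back
      } else if (sj >= ny) {
        if (bc_top == BC_PERIODIC) { sj -= ny; }
        else if (bc_top == BC_SLIP) { sj = ny - 1; sq = MIR[q]; }
        else { sj = ny - 1; sq = OPP[q]; shift = 0; }
      }
      src = gpost + GIDX(0, sj, sq);
      double* dst = g + GIDX(0, j, q);
      if (shift == 0) {
        std::copy(src, src + nx, dst);
      } else if (shift == 1) {
        dst[0] = src[nx - 1];
        std::copy(src, src + nx - 1, dst + 1);
      } else { // shift == -1
        std::copy(src + 1, src + nx, dst);
        dst[nx - 1] = src[0];
      }
    }
  }
  (void)xper;
}

// Raw moments (density and bare momentum, no force correction); the engine
// caches these so the Guo half-force velocity can be refreshed cheaply when
// the body force changes within the step cycle.
inline void moments_raw_core(const double* g, int nx, int ny,
                             double* rho, double* mx, double* my) {
  size_t nn = (size_t)nx * ny;
  const double *g0 = g, *g1 = g + nn, *g2 = g + 2 * nn, *g3 = g + 3 * nn,
    *g4 = g + 4 * nn, *g5 = g + 5 * nn, *g6 = g + 6 * nn, *g7 = g + 7 * nn,
    *g8 = g + 8 * nn;
  for (size_t k = 0; k < nn; ++k) {
    rho[k] = g0[k] + g1[k] + g2[k] + g3[k] + g4[k] + g5[k] + g6[k] + g7[k]
      + g8[k];
    mx[k] = (g1[k] + g5[k] + g8[k]) - (g3[k] + g6[k] + g7[k]);
    my[k] = (g2[k] + g5[k] + g6[k]) - (g4[k] + g7[k] + g8[k]);
  }
}

// Non-equilibrium extrapolation on a boundary column (side 0: i=0 from i=1;
// side 1: i=nx-1 from i=nx-2). ubx/uby length ny give the imposed wall/inlet
// velocity; if zero_gradient, the neighbor's velocity is copied instead
// (outflow). rho/ux/uy are current macroscopic fields; boundary column values
// are refreshed in place.
inline void nee_column(double* g, int nx, int ny, int side, bool zero_gradient,
                       const double* ubx, const double* uby,
                       double* rho, double* ux, double* uy) {
  int ib = (side == 0) ? 0 : nx - 1;
  int in = (side == 0) ? 1 : nx - 2;
  for (int j = 0; j < ny; ++j) {
    size_t kb = FIDX(ib, j), kn = FIDX(in, j);
    double rn = rho[kn];
    // velocity inlet: impose u, extrapolate density; outflow: pressure
    // outlet anchoring rho = 1 with zero-gradient velocity
    double rb = zero_gradient ? 1.0 : rn;
    double ubx_j = zero_gradient ? ux[kn] : ubx[j];
    double uby_j = zero_gradient ? uy[kn] : uby[j];
    for (int q = 0; q < 9; ++q) {
      double gneq = g[GIDX(in, j, q)] - feq_q(q, rn, ux[kn], uy[kn]);
      g[GIDX(ib, j, q)] = feq_q(q, rb, ubx_j, uby_j) + gneq;
    }
    rho[kb] = rb;
    ux[kb] = ubx_j;
    uy[kb] = uby_j;
  }
}

// Non-equilibrium extrapolation wall row (side 0: j=0; 1: j=ny-1).
// slip = false: no-slip (u = 0); slip = true: free slip (tangential velocity
// copied from the neighbor row, zero normal velocity) - a regularized slip
// closure that stays well-behaved at large relaxation times, where specular
// reflection lets non-equilibrium noise accumulate.
inline void nee_row(double* g, int nx, int ny, int side,
                    double* rho, double* ux, double* uy, bool slip = false) {
  int jb = (side == 0) ? 0 : ny - 1;
  int jn = (side == 0) ? 1 : ny - 2;
  for (int i = 0; i < nx; ++i) {
    size_t kb = FIDX(i, jb), kn = FIDX(i, jn);
    double rn = rho[kn];
    double ubx = slip ? ux[kn] : 0.0;
    for (int q = 0; q < 9; ++q) {
      double gneq = g[GIDX(i, jn, q)] - feq_q(q, rn, ux[kn], uy[kn]);
      g[GIDX(i, jb, q)] = feq_q(q, rn, ubx, 0.0) + gneq;
    }
    rho[kb] = rn;
    ux[kb] = ubx;
    uy[kb] = 0.0;
  }
}

#endif
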