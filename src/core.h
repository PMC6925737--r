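#ifndef CILIAFLOW_CORE_H
#define CILIAFLOW_CORE_H

#include <Rcpp.h>
#include <cmath>

// ---------------------------------------------------------------------------
// D2Q9 lattice constants. Velocity set: 0 rest; 1..4 axis; 5..8 diagonal.
// ---------------------------------------------------------------------------
static const int    EX[9]  = {0, 1, 0, -1,  0, 1, -1, -1,  1};
static const int    EY[9]  = {0, 0, 1,  0, -1, 1,  1, -1, -1};
static const double WQ[9]  = {4.0/9.0, 1.0/9.0, 1.0/9.0, 1.0/9.0, 1.0/9.0,
                              1.0/36.0, 1.0/36.0, 1.0/36.0, 1.0/36.0};
static const int    OPP[9] = {0, 3, 4, 1, 2, 7, 8, 5, 6}; // full reversal
static const int    MIR[9] = {0, 1, 4, 3, 2, 8, 7, 6, 5}; // y-mirror (specular)
#define CS2 (1.0/3.0)

// Boundary codes for the four edges
enum BCKind { BC_PERIODIC = 0, BC_NOSLIP_BB = 1, BC_SLIP = 2,
              BC_NOSLIP_NEE = 3, BC_INLET_NEE = 4, BC_OUTFLOW_NEE = 5,
              BC_SLIP_NEE = 6 };

// Incompressible (He-Luo) D2Q9 equilibrium with reference density rho0 = 1:
// g_eq = w_q [rho + e.u/cs2 + (e.u)^2/(2 cs4) - u.u/(2 cs2)].
// Identical to the compressible second-order form at rho = 1; removes the
// compressibility pressure-drop error in pressure-driven channels, where the
// density field carries the pressure gradient without scaling the velocity.
inline double feq_q(int q, double rho, double ux, double uy) {
  double eu = EX[q] * ux + EY[q] * uy;
  double u2 = ux * ux + uy * uy;
  return WQ[q] * (rho + eu / CS2 + 0.5 * eu * eu / (CS2 * CS2)
                  - 0.5 * u2 / CS2);
}

// Guo forcing term G_q = (1 - 1/(2 tau)) w_q [(e-u)/cs2 + (e.u)e/cs4] . f
inline double guo_q(int q, double ux, double uy, double fx, double fy,
                    double tau) {
  double pref = (1.0 - 0.5 / tau) * WQ[q];
  double eu = EX[q] * ux + EY[q] * uy;
  double ax = (EX[q] - ux) / CS2 + eu * EX[q] / (CS2 * CS2);
  double ay = (EY[q] - uy) / CS2 + eu * EY[q] / (CS2 * CS2);
  return pref * (ax * fx + ay * fy);
}

// ---------------------------------------------------------------------------
// Regularized delta kernels (1D factor). kind: 4 = Peskin 4-point cosine-free
// algebraic form, 2 = 2-point hat. Both satisfy discrete partition of unity.
// ---------------------------------------------------------------------------
// kind 4: Peskin 4-point; kind 3: cubic B-spline (same support, C^2-smooth,
// exact partition of unity - markedly less sub-grid "staircase" variation of
// the pairwise mobility for obliquely tilted fibers); kind 2: 2-point hat.
inline double ib_phi1(double r, int kind) {
  double a = std::fabs(r);
  if (kind == 2) {
    return (a < 1.0) ? 1.0 - a : 0.0;
  }
  if (kind == 3) {
    if (a >= 2.0) return 0.0;
    if (a < 1.0) return 2.0 / 3.0 - a * a + 0.5 * a * a * a;
    double b = 2.0 - a;
    return b * b * b / 6.0;
  }
  if (kind == 5) { // quintic B-spline: C^4, support 3, exact PoU
    if (a >= 3.0) return 0.0;
    double p3 = (3.0 - a) * (3.0 - a) * (3.0 - a) * (3.0 - a) * (3.0 - a);
    double v = p3;
    if (a < 2.0) {
      double p2 = (2.0 - a) * (2.0 - a) * (2.0 - a) * (2.0 - a) * (2.0 - a);
      v -= 6.0 * p2;
    }
    if (a < 1.0) {
      double p1 = (1.0 - a) * (1.0 - a) * (1.0 - a) * (1.0 - a) * (1.0 - a);
      v += 15.0 * p1;
    }
    return v / 120.0;
  }
  if (a >= 2.0) return 0.0;
  if (a < 1.0)
    return 0.125 * (3.0 - 2.0 * a + std::sqrt(1.0 + 4.0 * a - 4.0 * a * a));
  return 0.125 * (5.0 - 2.0 * a - std::sqrt(-7.0 + 12.0 * a - 4.0 * a * a));
}

inline int wrap_i(int i, int n) { int r = i % n; return (r < 0) ? r + n : r; }

// positive modulo (result in [0, b)); avoids libm fmod
inline double pmod(double a, double b) {
  double r = a - std::floor(a / b) * b;
  if (r >= b) r -= b;
  if (r < 0.0) r += b;
  return r;
}

// Membrane height h at each lattice column from an x-monotone polyline with
// unwrapped x spanning one channel period Lx = nx. Aborts on folding.
inline void membrane_height_core(const double* mx, const double* my, int n,
                                 int nx, double* h) {
  for (int k = 1; k < n; ++k)
    if (mx[k] <= mx[k - 1])
      Rcpp::stop("membrane folding: node x-coordinates are not strictly increasing");
  double x0 = mx[0];
  for (int i = 0; i < nx; ++i) {
    double xq = x0 + pmod(i - x0, (double)nx);
    int lo = (int)std::floor(xq - x0);
    if (lo > n - 1) lo = n - 1;
    while (lo > 0 && mx[lo] > xq) --lo;
    while (lo < n - 1 && mx[lo + 1] <= xq) ++lo;
    double xa, ya, xb, yb;
    if (lo >= n - 1) {
      xa = mx[n - 1]; ya = my[n - 1];
      xb = mx[0] + nx; yb = my[0];
    } else {
      xa = mx[lo]; ya = my[lo];
      xb = mx[lo + 1]; yb = my[lo + 1];
    }
    double w = (xb > xa) ? (xq - xa) / (xb - xa) : 0.0;
    h[i] = ya + w * (yb - ya);
  }
}

// Smoothed Heaviside with half-width hw (transition band 2*hw)
inline double smooth_heaviside(double r, double hw) {
  double x = r / hw;
  if (x <= -1.0) return 0.0;
  if (x >=  1.0) return 1.0;
  return 0.5 * (1.0 + x + std::sin(M_PI * x) / M_PI);
}

#endif
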