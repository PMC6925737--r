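#include "core.h"
#include "step.h"
#include "ib.h"
#include "fiber.h"
#include "stress.h"

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cf_equilibrium(NumericMatrix rho, NumericMatrix ux,
                             NumericMatrix uy) {
  int nx = rho.nrow(), ny = rho.ncol();
  NumericVector g(Dimension(nx, ny, 9));
  for (int q = 0; q < 9; ++q)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        g[GIDX(i, j, q)] = feq_q(q, rho(i, j), ux(i, j), uy(i, j));
  return g;
}

// [[Rcpp::export]]
NumericVector cf_guo_source(NumericMatrix ux, NumericMatrix uy,
                            NumericMatrix fx, NumericMatrix fy, double tau) {
  int nx = ux.nrow(), ny = ux.ncol();
  NumericVector G(Dimension(nx, ny, 9));
  for (int q = 0; q < 9; ++q)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        G[GIDX(i, j, q)] = guo_q(q, ux(i, j), uy(i, j), fx(i, j), fy(i, j),
                                 tau);
  return G;
}

// [[Rcpp::export]]
List cf_macroscopic(NumericVector g, NumericMatrix fx, NumericMatrix fy) {
  IntegerVector dim = g.attr("dim");
  int nx = dim[0], ny = dim[1];
  NumericMatrix rho(nx, ny), ux(nx, ny), uy(nx, ny);
  macroscopic_core(REAL(g), REAL(fx), REAL(fy), nx, ny,
                   REAL(rho), REAL(ux), REAL(uy));
  return List::create(_["rho"] = rho, _["ux"] = ux, _["uy"] = uy);
}

// One full LBM update: macroscopic moments -> BGK collision + Guo forcing ->
// streaming with wall closures -> non-equilibrium-extrapolation edges.
// bc = int[4] (bottom, top, left, right); inlet_ux/uy used by BC_INLET_NEE.
// [[Rcpp::export]]
List cf_lbm_step(NumericVector g, NumericMatrix fx, NumericMatrix fy,
                 NumericMatrix tau, IntegerVector bc,
                 NumericVector inlet_ux, NumericVector inlet_uy,
                 int nsteps = 1) {
  IntegerVector dim = g.attr("dim");
  int nx = dim[0], ny = dim[1];
  NumericVector gw = clone(g);
  NumericVector gpost(g.size());
  NumericMatrix rho(nx, ny), ux(nx, ny), uy(nx, ny);
  for (int s = 0; s < nsteps; ++s) {
    macroscopic_core(REAL(gw), REAL(fx), REAL(fy), nx, ny,
                     REAL(rho), REAL(ux), REAL(uy));
    collide_stream_core(REAL(gw), REAL(gpost), nx, ny, REAL(rho), REAL(ux),
                        REAL(uy), REAL(fx), REAL(fy), REAL(tau),
                        bc[0], bc[1], bc[2], bc[3]);
    macroscopic_core(REAL(gw), REAL(fx), REAL(fy), nx, ny,
                     REAL(rho), REAL(ux), REAL(uy));
    if (bc[2] == BC_INLET_NEE)
      nee_column(REAL(gw), nx, ny, 0, false, REAL(inlet_ux), REAL(inlet_uy),
                 REAL(rho), REAL(ux), REAL(uy));
    if (bc[2] == BC_OUTFLOW_NEE)
      nee_column(REAL(gw), nx, ny, 0, true, REAL(inlet_ux), REAL(inlet_uy),
                 REAL(rho), REAL(ux), REAL(uy));
    if (bc[3] == BC_INLET_NEE)
      nee_column(REAL(gw), nx, ny, 1, false, REAL(inlet_ux), REAL(inlet_uy),
                 REAL(rho), REAL(ux), REAL(uy));
    if (bc[3] == BC_OUTFLOW_NEE)
      nee_column(REAL(gw), nx, ny, 1, true, REAL(inlet_ux), REAL(inlet_uy),
                 REAL(rho), REAL(ux), REAL(uy));
    if (bc[0] == BC_NOSLIP_NEE || bc[0] == BC_SLIP_NEE)
      nee_row(REAL(gw), nx, ny, 0, REAL(rho), REAL(ux), REAL(uy),
              bc[0] == BC_SLIP_NEE);
    if (bc[1] == BC_NOSLIP_NEE || bc[1] == BC_SLIP_NEE)
      nee_row(REAL(gw), nx, ny, 1, REAL(rho), REAL(ux), REAL(uy),
              bc[1] == BC_SLIP_NEE);
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (rho(i, j) <= 0.0 || !std::isfinite(rho(i, j)))
          stop("LBM blow-up: non-positive or non-finite density at node (%d, %d), step %d",
               i + 1, j + 1, s + 1);
      }
  }
  return List::create(_["g"] = gw, _["rho"] = rho, _["ux"] = ux,
                      _["uy"] = uy);
}

// [[Rcpp::export]]
NumericVector cf_ib_phi(NumericVector r, int kind) {
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = ib_phi1(r[i], kind);
  return out;
}

// [[Rcpp::export]]
List cf_spread(NumericMatrix X, NumericMatrix F, int nx, int ny, double ds,
               int kind) {
  NumericMatrix fx(nx, ny), fy(nx, ny);
  for (int s = 0; s < X.nrow(); ++s) {
    if (X(s, 1) < -0.5 || X(s, 1) > ny - 0.5)
      stop("spread_force: Lagrangian point %d outside domain in y", s + 1);
    spread_point(X(s, 0), X(s, 1), F(s, 0), F(s, 1), ds, kind, nx, ny,
                 REAL(fx), REAL(fy));
  }
  return List::create(_["fx"] = fx, _["fy"] = fy);
}

// [[Rcpp::export]]
NumericMatrix cf_interp(NumericMatrix ux, NumericMatrix uy, NumericMatrix X,
                        int kind) {
  int nx = ux.nrow(), ny = ux.ncol();
  NumericMatrix U(X.nrow(), 2);
  for (int s = 0; s < X.nrow(); ++s) {
    double Uxs, Uys;
    interp_point(X(s, 0), X(s, 1), kind, nx, ny, REAL(ux), REAL(uy),
                 &Uxs, &Uys);
    U(s, 0) = Uxs;
    U(s, 1) = Uys;
  }
  return U;
}

// [[Rcpp::export]]
NumericMatrix cf_fiber_stretch(NumericMatrix X, double ks, double ds,
                               bool closed, double Lx) {
  int n = X.nrow();
  NumericMatrix F(n, 2);
  std::vector<double> x(n), y(n), fx(n), fy(n);
  for (int k = 0; k < n; ++k) { x[k] = X(k, 0); y[k] = X(k, 1); }
  stretch_force_core(x.data(), y.data(), n, ks, ds, closed, Lx,
                     fx.data(), fy.data());
  for (int k = 0; k < n; ++k) { F(k, 0) = fx[k]; F(k, 1) = fy[k]; }
  return F;
}

// [[Rcpp::export]]
NumericMatrix cf_fiber_bend(NumericMatrix X, double kb, double ds,
                            bool closed, double Lx) {
  int n = X.nrow();
  NumericMatrix F(n, 2);
  std::vector<double> x(n), y(n), fx(n), fy(n);
  for (int k = 0; k < n; ++k) { x[k] = X(k, 0); y[k] = X(k, 1); }
  bend_force_core(x.data(), y.data(), n, kb, ds, closed, Lx,
                  fx.data(), fy.data());
  for (int k = 0; k < n; ++k) { F(k, 0) = fx[k]; F(k, 1) = fy[k]; }
  return F;
}

// [[Rcpp::export]]
List cf_velocity_gradient(NumericMatrix ux, NumericMatrix uy, bool xper,
                          bool yper) {
  int nx = ux.nrow(), ny = ux.ncol();
  NumericMatrix Lxx(nx, ny), Lxy(nx, ny), Lyx(nx, ny), Lyy(nx, ny);
  velocity_gradient_core(REAL(ux), REAL(uy), nx, ny, xper, yper,
                         REAL(Lxx), REAL(Lxy), REAL(Lyx), REAL(Lyy));
  return List::create(_["Lxx"] = Lxx, _["Lxy"] = Lxy, _["Lyx"] = Lyx,
                      _["Lyy"] = Lyy);
}

// [[Rcpp::export]]
List cf_stress_advance(NumericMatrix sxx, NumericMatrix sxy,
                       NumericMatrix syy, NumericMatrix ux, NumericMatrix uy,
                       NumericMatrix etaE, double lambda, double dt,
                       bool xper, int nsteps = 1, double kappa = 0.0) {
  int nx = ux.nrow(), ny = ux.ncol();
  NumericMatrix wxx = clone(sxx), wxy = clone(sxy), wyy = clone(syy);
  NumericMatrix Lxx(nx, ny), Lxy(nx, ny), Lyx(nx, ny), Lyy(nx, ny);
  velocity_gradient_core(REAL(ux), REAL(uy), nx, ny, xper, false,
                         REAL(Lxx), REAL(Lxy), REAL(Lyx), REAL(Lyy));
  for (int s = 0; s < nsteps; ++s)
    stress_advance_core(REAL(wxx), REAL(wxy), REAL(wyy), REAL(ux), REAL(uy),
                        REAL(Lxx), REAL(Lxy), REAL(Lyx), REAL(Lyy),
                        REAL(etaE), lambda, dt, nx, ny, xper, kappa);
  return List::create(_["sxx"] = wxx, _["sxy"] = wxy, _["syy"] = wyy);
}

// [[Rcpp::export]]
List cf_stress_divergence(NumericMatrix sxx, NumericMatrix sxy,
                          NumericMatrix syy, NumericMatrix ind, bool xper) {
  int nx = sxx.nrow(), ny = sxx.ncol();
  NumericMatrix fx(nx, ny), fy(nx, ny);
  stress_divergence_core(REAL(sxx), REAL(sxy), REAL(syy), REAL(ind),
                         nx, ny, xper, REAL(fx), REAL(fy));
  return List::create(_["fx"] = fx, _["fy"] = fy);
}

// Membrane height h(x) at each lattice column from an x-monotone polyline
// (unwrapped x spanning one channel period Lx = nx).
// [[Rcpp::export]]
NumericVector cf_membrane_height(NumericVector mx, NumericVector my, int nx) {
  NumericVector h(nx);
  membrane_height_core(REAL(mx), REAL(my), mx.size(), nx, REAL(h));
  return h;
}

// Smoothed-Heaviside layer indicator from per-column membrane heights.
// [[Rcpp::export]]
NumericMatrix cf_layer_indicator(NumericVector h, int ny, double hw) {
  int nx = h.size();
  NumericMatrix ind(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      ind(i, j) = smooth_heaviside(j - h[i], hw);
  return ind;
}
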