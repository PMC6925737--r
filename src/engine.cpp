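#include "core.h"
#include "step.h"
#include "ib.h"
#include "fiber.h"
#include "stress.h"

using namespace Rcpp;

// Fused time-stepping loop for the mucociliary-clearance model and the
// Poiseuille validation channel. State and configuration travel as R lists;
// all per-step work happens here. Per step:
//   (1) rebuild layer map from the membrane (two-layer mode)
//   (2) fiber elastic + driving forces, particle penalty + repulsion forces
//   (3) spread all Lagrangian forces to the lattice
//   (4) elastic-stress divergence force (viscoelastic layer)
//   (5) BGK collide + stream + boundary closure + NEE edges, macroscopic
//   (6) advance the Oldroyd-B elastic stress
//   (7) interpolate velocities, advect fibers/membrane/tracers
//   (8) rigid-particle Newton update
//   (9) sampling, blow-up checks
// [[Rcpp::export]]
List cf_engine_run(List state, List cfg, int nsteps) {
  // --- configuration ----------------------------------------------------
  const int nx = as<int>(cfg["nx"]), ny = as<int>(cfg["ny"]);
  const size_t nn = (size_t)nx * ny;
  IntegerVector bc = cfg["bc"];
  const int kern = as<int>(cfg["kernel"]);
  const double ds = as<double>(cfg["ds"]);
  const bool two_layer = as<bool>(cfg["two_layer"]);
  const bool use_stress = as<bool>(cfg["use_stress"]);
  const double lambda = as<double>(cfg["lambda"]);
  const double nu_pcl = as<double>(cfg["nu_pcl"]);
  const double stress_kappa = cfg.containsElementNamed("stress_kappa")
    ? as<double>(cfg["stress_kappa"]) : 0.0;
  const double nu_mln = as<double>(cfg["nu_mln"]);
  const double etaE_ml = as<double>(cfg["etaE_ml"]);
  const double ind_hw = as<double>(cfg["ind_hw"]);
  const double steps_per_T = as<double>(cfg["steps_per_T"]);
  const int sample_every = as<int>(cfg["sample_every"]);
  const double ks = as<double>(cfg["ks"]), kb = as<double>(cfg["kb"]);
  const double ksl = as<double>(cfg["ksl"]);
  // per-node cap on the penalty driving force: regularizes the rare frames
  // where out-of-phase neighboring cilia overlap within a kernel width and
  // would otherwise escalate opposing forces (CFL blow-up); inactive in
  // normal tracking (|F_c| ~ 0.1)
  const double fc_max = cfg.containsElementNamed("fc_max")
    ? as<double>(cfg["fc_max"]) : 1.0;
  const double mem_ds = cfg.containsElementNamed("mem_ds")
    ? as<double>(cfg["mem_ds"]) : 1.0;
  const double mem_ks = cfg.containsElementNamed("mem_ks")
    ? as<double>(cfg["mem_ks"]) : ks;
  const double mem_kb = cfg.containsElementNamed("mem_kb")
    ? as<double>(cfg["mem_kb"]) : kb;
  // membrane rest-length fraction < 1 pre-tensions the chain (interfacial
  // tension T0 = mem_ks (1/frac - 1)), flattening long-wavelength waves
  const double mem_rest = cfg.containsElementNamed("mem_rest")
    ? as<double>(cfg["mem_rest"]) : 1.0;
  const int layer_every = cfg.containsElementNamed("layer_every")
    ? as<int>(cfg["layer_every"]) : 4; // membrane moves ~1e-3 dx per step

  // beat posture table: n_phase x n_nodes x 2, positions relative to root
  NumericVector beat = cfg.containsElementNamed("beat_table")
    ? as<NumericVector>(cfg["beat_table"]) : NumericVector(0);
  int n_phase = 0, n_cnodes = 0;
  if (beat.size() > 0) {
    IntegerVector bd = beat.attr("dim");
    n_phase = bd[0];
    n_cnodes = bd[1];
  }
  NumericVector roots = cfg.containsElementNamed("roots")
    ? as<NumericVector>(cfg["roots"]) : NumericVector(0);
  NumericVector phase_off = cfg.containsElementNamed("phase_off")
    ? as<NumericVector>(cfg["phase_off"]) : NumericVector(0);

  // particles
  const bool has_part = cfg.containsElementNamed("particle_radius");
  double pr = 0, pmass = 1, pinertia = 1, pgamma = 0.2, repC = 1,
         repd = 2.0, pgrav = 0.0;
  int pns = 0;
  if (has_part) {
    pr = as<double>(cfg["particle_radius"]);
    pns = as<int>(cfg["particle_ns"]);
    pmass = as<double>(cfg["particle_mass"]);
    pinertia = as<double>(cfg["particle_inertia"]);
    pgamma = as<double>(cfg["particle_gamma"]);
    repC = as<double>(cfg["rep_C"]);
    repd = as<double>(cfg["rep_dcut"]);
    pgrav = as<double>(cfg["particle_grav"]); // (rho_p - rho_f) V_p g, y-dir
  }

  NumericVector inlet_ux = cfg.containsElementNamed("inlet_ux")
    ? as<NumericVector>(cfg["inlet_ux"]) : NumericVector(ny);
  NumericVector inlet_uy(ny);
  // inflow stress (Dirichlet): the hyperbolic stress transport needs the
  // incoming elastic stress prescribed at a velocity inlet
  bool has_inlet_stress = cfg.containsElementNamed("inlet_sxx");
  NumericVector in_sxx, in_sxy, in_syy;
  if (has_inlet_stress) {
    in_sxx = as<NumericVector>(cfg["inlet_sxx"]);
    in_sxy = as<NumericVector>(cfg["inlet_sxy"]);
    in_syy = as<NumericVector>(cfg["inlet_syy"]);
  }

  // --- state ------------------------------------------------------------
  NumericVector g = clone(as<NumericVector>(state["g"]));
  NumericVector gpost(g.size());
  NumericMatrix rho = clone(as<NumericMatrix>(state["rho"]));
  NumericMatrix ux = clone(as<NumericMatrix>(state["ux"]));
  NumericMatrix uy = clone(as<NumericMatrix>(state["uy"]));
  NumericMatrix tau = clone(as<NumericMatrix>(state["tau"]));
  NumericMatrix ind = clone(as<NumericMatrix>(state["ind"]));
  NumericMatrix etaE = clone(as<NumericMatrix>(state["etaE"]));
  NumericMatrix sxx(nx, ny), sxy(nx, ny), syy(nx, ny);
  if (use_stress) {
    sxx = clone(as<NumericMatrix>(state["sxx"]));
    sxy = clone(as<NumericMatrix>(state["sxy"]));
    syy = clone(as<NumericMatrix>(state["syy"]));
  }
  int t = as<int>(state["t"]);

  // membrane (closed periodic chain, unwrapped x)
  bool has_mem = state.containsElementNamed("mem_x") &&
    !Rf_isNull(state["mem_x"]);
  NumericVector mem_x, mem_y;
  double mem_y0 = 0.0;
  if (has_mem) {
    mem_x = clone(as<NumericVector>(state["mem_x"]));
    mem_y = clone(as<NumericVector>(state["mem_y"]));
    if (cfg.containsElementNamed("mem_y0")) {
      mem_y0 = as<double>(cfg["mem_y0"]);
    } else {
      for (int k = 0; k < mem_y.size(); ++k) mem_y0 += mem_y[k];
      mem_y0 /= mem_y.size();
    }
  }

  // cilia: list of n x 2 matrices
  List cilia_in = state.containsElementNamed("cilia")
    ? as<List>(state["cilia"]) : List(0);
  int ncil = cilia_in.size();
  std::vector<std::vector<double>> cx(ncil), cy(ncil);
  for (int c = 0; c < ncil; ++c) {
    NumericMatrix Xc = cilia_in[c];
    cx[c].assign(Xc.nrow(), 0.0);
    cy[c].assign(Xc.nrow(), 0.0);
    for (int k = 0; k < Xc.nrow(); ++k) { cx[c][k] = Xc(k, 0); cy[c][k] = Xc(k, 1); }
  }

  // tracers (wrapped + unwrapped x)
  bool has_tr = state.containsElementNamed("tr_x") && !Rf_isNull(state["tr_x"]);
  NumericVector tr_x, tr_y, tr_xu;
  if (has_tr) {
    tr_x = clone(as<NumericVector>(state["tr_x"]));
    tr_y = clone(as<NumericVector>(state["tr_y"]));
    tr_xu = clone(as<NumericVector>(state["tr_xu"]));
  }

  // particles
  bool has_pstate = state.containsElementNamed("p_x") && !Rf_isNull(state["p_x"]);
  NumericVector p_x, p_y, p_ux, p_uy, p_om, p_ang;
  int np = 0;
  if (has_pstate && has_part) {
    p_x = clone(as<NumericVector>(state["p_x"]));
    p_y = clone(as<NumericVector>(state["p_y"]));
    p_ux = clone(as<NumericVector>(state["p_ux"]));
    p_uy = clone(as<NumericVector>(state["p_uy"]));
    p_om = clone(as<NumericVector>(state["p_om"]));
    p_ang = clone(as<NumericVector>(state["p_ang"]));
    np = p_x.size();
  }

  // --- logs ---------------------------------------------------------------
  int nsamp = nsteps / sample_every + 1;
  std::vector<double> log_t, log_trx, log_py, log_mass, log_maxu,
    log_strain, log_track;
  log_t.reserve(nsamp);
  NumericMatrix log_part_y(np, nsamp), log_part_x(np, nsamp);
  int isamp = 0;
  double max_strain = 0.0, max_track = 0.0;

  // scratch
  NumericMatrix fx(nx, ny), fy(nx, ny);
  std::vector<double> mxr(nn), myr(nn);
  moments_raw_core(REAL(g), nx, ny, REAL(rho), mxr.data(), myr.data());
  int max_cn = 0;
  for (int c = 0; c < ncil; ++c) max_cn = std::max(max_cn, (int)cx[c].size());
  std::vector<double> fsx(std::max(max_cn, 8)), fsy(std::max(max_cn, 8)),
    fbx(std::max(max_cn, 8)), fby(std::max(max_cn, 8));
  std::vector<std::vector<double>> cfx(ncil), cfy(ncil);
  for (int c = 0; c < ncil; ++c) {
    cfx[c].assign(cx[c].size(), 0.0);
    cfy[c].assign(cx[c].size(), 0.0);
  }
  int nm = has_mem ? mem_x.size() : 0;
  std::vector<double> mfx(std::max(nm, 1)), mfy(std::max(nm, 1)),
    mbx(std::max(nm, 1)), mby(std::max(nm, 1));
  double ds_p = (pns > 0) ? 2.0 * M_PI * pr / pns : 0.0;
  std::vector<double> pfx(std::max(np, 1)), pfy(std::max(np, 1)),
    ptq(std::max(np, 1));

  const double dt = 1.0;

  for (int step = 0; step < nsteps; ++step) {
    // (1) layer map from membrane
    if (two_layer && has_mem && step % layer_every == 0) {
      // enforce the exact invariant of the continuous problem: the area
      // below a material curve advected by a divergence-free field is
      // conserved (the discrete interpolated field is not exactly
      // solenoidal at the kernel scale and the marker curve would slowly
      // drift otherwise)
      double hbar = 0.0;
      for (int k = 0; k < nm; ++k) hbar += mem_y[k];
      hbar /= nm;
      for (int k = 0; k < nm; ++k) mem_y[k] += mem_y0 - hbar;
      // untangle incipient folds: restore a minimal x-gap between adjacent
      // nodes without touching the chain's bulk tangential motion
      for (int k = 0; k < nm; ++k) {
        int kp = (k + 1) % nm;
        double xa = mem_x[k];
        double xb = mem_x[kp] + ((kp == 0) ? (double)nx : 0.0);
        if (xb - xa < 0.2) {
          double mid = 0.5 * (xa + xb);
          mem_x[k] = mid - 0.1;
          mem_x[kp] = mid + 0.1 - ((kp == 0) ? (double)nx : 0.0);
        }
      }
      std::vector<double> h(nx);
      membrane_height_core(REAL(mem_x), REAL(mem_y), nm, nx, h.data());
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          double id = smooth_heaviside(j - h[i], ind_hw);
          ind(i, j) = id;
          double nu = nu_pcl + (nu_mln - nu_pcl) * id;
          tau(i, j) = 3.0 * nu + 0.5;
          etaE(i, j) = etaE_ml * id;
        }
    }

    // (2) zero force field
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);

    // cilium forces: stretching + bending + virtual-spring driving
    double tphase = (t + 1) / steps_per_T;
    for (int c = 0; c < ncil; ++c) {
      int n = cx[c].size();
      stretch_force_core(cx[c].data(), cy[c].data(), n, ks, ds, false, 0.0,
                         fsx.data(), fsy.data());
      bend_force_core(cx[c].data(), cy[c].data(), n, kb, ds, false, 0.0,
                      fbx.data(), fby.data());
      // strain diagnostic
      for (int k = 0; k < n - 1; ++k) {
        double dxk = cx[c][k + 1] - cx[c][k], dyk = cy[c][k + 1] - cy[c][k];
        double st = std::fabs(std::sqrt(dxk * dxk + dyk * dyk) / ds - 1.0);
        if (st > max_strain) max_strain = st;
      }
      // virtual cilium posture at this cilium's phase
      double ph = pmod(tphase + phase_off[c], 1.0);
      double pidx = ph * n_phase;
      int i0 = (int)std::floor(pidx) % n_phase;
      int i1 = (i0 + 1) % n_phase;
      double w = pidx - std::floor(pidx);
      for (int k = 0; k < n; ++k) {
        double Yx = roots[c]
          + (1.0 - w) * beat[i0 + n_phase * (k + (size_t)n_cnodes * 0)]
          + w * beat[i1 + n_phase * (k + (size_t)n_cnodes * 0)];
        double Yy = (1.0 - w) * beat[i0 + n_phase * (k + (size_t)n_cnodes * 1)]
          + w * beat[i1 + n_phase * (k + (size_t)n_cnodes * 1)];
        double fcx = ksl * (Yx - cx[c][k]);
        double fcy = ksl * (Yy - cy[c][k]);
        double fcm = std::sqrt(fcx * fcx + fcy * fcy);
        if (fcm > fc_max) { fcx *= fc_max / fcm; fcy *= fc_max / fcm; }
        double trk = std::sqrt((Yx - cx[c][k]) * (Yx - cx[c][k])
                               + (Yy - cy[c][k]) * (Yy - cy[c][k]));
        if (trk > max_track) max_track = trk;
        cfx[c][k] = fsx[k] + fbx[k] + fcx;
        cfy[c][k] = fsy[k] + fby[k] + fcy;
      }
    }

    // membrane forces (closed chain across the periodic seam)
    if (has_mem) {
      stretch_force_core(mem_x.begin(), mem_y.begin(), nm, mem_ks,
                         mem_ds * mem_rest, true, (double)nx,
                         mfx.data(), mfy.data());
      bend_force_core(mem_x.begin(), mem_y.begin(), nm, mem_kb, mem_ds, true,
                      (double)nx, mbx.data(), mby.data());
      for (int k = 0; k < nm; ++k) { mfx[k] += mbx[k]; mfy[k] += mby[k]; }
    }

    // particles: penalty (direct-forcing) surface coupling + repulsion
    if (np > 0) {
      for (int pI = 0; pI < np; ++pI) {
        double Fh_x = 0.0, Fh_y = 0.0, Tq = 0.0;
        for (int sI = 0; sI < pns; ++sI) {
          double th = p_ang[pI] + 2.0 * M_PI * sI / pns;
          double rx = pr * std::cos(th), ry = pr * std::sin(th);
          double Xs = p_x[pI] + rx, Ys = p_y[pI] + ry;
          double ufs, vfs;
          interp_point(Xs, Ys, kern, nx, ny, REAL(ux), REAL(uy), &ufs, &vfs);
          double Urx = p_ux[pI] - p_om[pI] * ry;
          double Ury = p_uy[pI] + p_om[pI] * rx;
          double fpx = pgamma * (Urx - ufs); // force on fluid
          double fpy = pgamma * (Ury - vfs);
          spread_point(Xs, Ys, fpx, fpy, ds_p, kern, nx, ny,
                       REAL(fx), REAL(fy));
          Fh_x -= fpx * ds_p; // reaction on particle
          Fh_y -= fpy * ds_p;
          Tq -= (rx * fpy - ry * fpx) * ds_p;
        }
        // short-range repulsion: walls
        double Fr_x = 0.0, Fr_y = 0.0;
        double gap_b = p_y[pI] - pr; // bottom wall at y = 0
        if (gap_b < repd) {
          double s = (repd - std::max(gap_b, 0.0)) / repd;
          Fr_y += repC * s * s;
        }
        double gap_t = (ny - 1.0) - (p_y[pI] + pr);
        if (gap_t < repd) {
          double s = (repd - std::max(gap_t, 0.0)) / repd;
          Fr_y -= repC * s * s;
        }
        // particle-particle
        for (int pj = 0; pj < np; ++pj) {
          if (pj == pI) continue;
          double dxp = p_x[pI] - p_x[pj];
          dxp -= nx * std::round(dxp / nx); // minimum image in x
          double dyp = p_y[pI] - p_y[pj];
          double dist = std::sqrt(dxp * dxp + dyp * dyp);
          double gap = dist - 2.0 * pr;
          if (gap < repd && dist > 1e-12) {
            double s = (repd - std::max(gap, 0.0)) / repd;
            double fmag = repC * s * s;
            Fr_x += fmag * dxp / dist;
            Fr_y += fmag * dyp / dist;
          }
        }
        // particle-cilium (reaction delivered to the cilium node)
        for (int c = 0; c < ncil; ++c) {
          int n = cx[c].size();
          for (int k = 0; k < n; ++k) {
            double dxp = p_x[pI] - cx[c][k];
            dxp -= nx * std::round(dxp / nx);
            double dyp = p_y[pI] - cy[c][k];
            double dist = std::sqrt(dxp * dxp + dyp * dyp);
            double gap = dist - pr;
            if (gap < repd && dist > 1e-12) {
              double s = (repd - std::max(gap, 0.0)) / repd;
              double fmag = repC * s * s;
              Fr_x += fmag * dxp / dist;
              Fr_y += fmag * dyp / dist;
              cfx[c][k] -= fmag * dxp / dist;
              cfy[c][k] -= fmag * dyp / dist;
            }
          }
        }
        pfx[pI] = Fh_x + Fr_x;
        pfy[pI] = Fh_y + Fr_y + pgrav;
        ptq[pI] = Tq;
      }
    }

    // (3) spread fiber forces
    for (int c = 0; c < ncil; ++c) {
      int n = cx[c].size();
      for (int k = 0; k < n; ++k)
        spread_point(cx[c][k], cy[c][k], cfx[c][k], cfy[c][k], ds, kern,
                     nx, ny, REAL(fx), REAL(fy));
    }
    if (has_mem)
      for (int k = 0; k < nm; ++k)
        spread_point(pmod(mem_x[k], (double)nx), mem_y[k],
                     mfx[k], mfy[k], mem_ds, kern, nx, ny,
                     REAL(fx), REAL(fy));

    // (4) elastic-stress force
    if (use_stress)
      stress_divergence_core(REAL(sxx), REAL(sxy), REAL(syy), REAL(ind),
                             nx, ny, bc[2] == BC_PERIODIC,
                             REAL(fx), REAL(fy));

    // (5) LBM update; velocity carries the Guo half-force correction with
    // this step's freshly accumulated force
    for (size_t k = 0; k < nn; ++k) {
      REAL(ux)[k] = mxr[k] + 0.5 * REAL(fx)[k];
      REAL(uy)[k] = myr[k] + 0.5 * REAL(fy)[k];
    }
    collide_stream_core(REAL(g), REAL(gpost), nx, ny, REAL(rho), REAL(ux),
                        REAL(uy), REAL(fx), REAL(fy), REAL(tau),
                        bc[0], bc[1], bc[2], bc[3]);
    moments_raw_core(REAL(g), nx, ny, REAL(rho), mxr.data(), myr.data());
    for (size_t k = 0; k < nn; ++k) {
      REAL(ux)[k] = mxr[k] + 0.5 * REAL(fx)[k];
      REAL(uy)[k] = myr[k] + 0.5 * REAL(fy)[k];
    }
    if (bc[2] == BC_INLET_NEE)
      nee_column(REAL(g), nx, ny, 0, false, REAL(inlet_ux), REAL(inlet_uy),
                 REAL(rho), REAL(ux), REAL(uy));
    if (bc[3] == BC_OUTFLOW_NEE)
      nee_column(REAL(g), nx, ny, 1, true, REAL(inlet_ux), REAL(inlet_uy),
                 REAL(rho), REAL(ux), REAL(uy));
    if (bc[0] == BC_NOSLIP_NEE || bc[0] == BC_SLIP_NEE)
      nee_row(REAL(g), nx, ny, 0, REAL(rho), REAL(ux), REAL(uy),
              bc[0] == BC_SLIP_NEE);
    if (bc[1] == BC_NOSLIP_NEE || bc[1] == BC_SLIP_NEE)
      nee_row(REAL(g), nx, ny, 1, REAL(rho), REAL(ux), REAL(uy),
              bc[1] == BC_SLIP_NEE);
    if (bc[0] >= BC_NOSLIP_NEE || bc[1] >= BC_NOSLIP_NEE
        || bc[2] >= BC_NOSLIP_NEE || bc[3] >= BC_NOSLIP_NEE) {
      // NEE rewrote edge velocities; keep cached raw moments consistent
      for (int j = 0; j < ny; ++j)
        for (int i : {0, nx - 1}) {
          size_t k = i + (size_t)nx * j;
          mxr[k] = REAL(ux)[k] - 0.5 * REAL(fx)[k];
          myr[k] = REAL(uy)[k] - 0.5 * REAL(fy)[k];
        }
      for (int i = 0; i < nx; ++i)
        for (int j : {0, ny - 1}) {
          size_t k = i + (size_t)nx * j;
          mxr[k] = REAL(ux)[k] - 0.5 * REAL(fx)[k];
          myr[k] = REAL(uy)[k] - 0.5 * REAL(fy)[k];
        }
    }

    // (6) Oldroyd-B elastic stress
    if (use_stress) {
      stress_advance_fused(REAL(sxx), REAL(sxy), REAL(syy), REAL(ux),
                           REAL(uy), REAL(etaE), lambda, dt, nx, ny,
                           bc[2] == BC_PERIODIC, stress_kappa);
      if (has_inlet_stress && bc[2] == BC_INLET_NEE)
        for (int j = 0; j < ny; ++j) {
          sxx(0, j) = in_sxx[j];
          sxy(0, j) = in_sxy[j];
          syy(0, j) = in_syy[j];
        }
    }

    // (7) advect Lagrangian structures (forward Euler, root nodes clamped)
    for (int c = 0; c < ncil; ++c) {
      int n = cx[c].size();
      for (int k = 1; k < n; ++k) { // node 0 anchored to the wall
        double Uxs, Uys;
        interp_point(cx[c][k], cy[c][k], kern, nx, ny, REAL(ux), REAL(uy),
                     &Uxs, &Uys);
        cx[c][k] += Uxs * dt;
        cy[c][k] += Uys * dt;
        if (cy[c][k] < 0.0) cy[c][k] = 0.0;
      }
    }
    if (has_mem) {
      for (int k = 0; k < nm; ++k) {
        double Uxs, Uys;
        interp_point(pmod(mem_x[k], (double)nx), mem_y[k], kern, nx, ny,
                     REAL(ux), REAL(uy), &Uxs, &Uys);
        mem_x[k] += Uxs * dt;
        mem_y[k] += Uys * dt;
      }
      // keep the chain's unwrapped frame anchored near [0, nx)
      if (mem_x[0] >= nx)
        for (int k = 0; k < nm; ++k) mem_x[k] -= nx;
      if (mem_x[0] < -(double)nx)
        for (int k = 0; k < nm; ++k) mem_x[k] += nx;
    }
    if (has_tr) {
      for (int k = 0; k < tr_x.size(); ++k) {
        double Uxs, Uys;
        interp_point(tr_x[k], tr_y[k], kern, nx, ny, REAL(ux), REAL(uy),
                     &Uxs, &Uys);
        tr_xu[k] += Uxs * dt;
        tr_x[k] = pmod(tr_x[k] + Uxs * dt, (double)nx);
        tr_y[k] = std::min(std::max(tr_y[k] + Uys * dt, 0.0), ny - 1.0);
      }
    }

    // (8) particle Newton update (explicit; rigid surface regenerated from
    // center + angle so the circle is exact by construction)
    for (int pI = 0; pI < np; ++pI) {
      p_ux[pI] += pfx[pI] / pmass * dt;
      p_uy[pI] += pfy[pI] / pmass * dt;
      p_om[pI] += ptq[pI] / pinertia * dt;
      p_x[pI] = pmod(p_x[pI] + p_ux[pI] * dt, (double)nx);
      p_y[pI] += p_uy[pI] * dt;
      p_ang[pI] += p_om[pI] * dt;
    }

    ++t;

    // (9) sampling + blow-up detection
    if (step % sample_every == 0 || step == nsteps - 1) {
      double mass = 0.0, maxu = 0.0, minrho = 1e300;
      for (size_t k = 0; k < nn; ++k) {
        mass += REAL(rho)[k];
        double sp = std::sqrt(REAL(ux)[k] * REAL(ux)[k]
                              + REAL(uy)[k] * REAL(uy)[k]);
        if (sp > maxu) maxu = sp;
        if (REAL(rho)[k] < minrho) minrho = REAL(rho)[k];
      }
      if (!std::isfinite(mass) || minrho <= 0.0)
        stop("blow-up at step %d: min(rho) = %g, total mass = %g",
             t, minrho, mass);
      if (maxu > 0.5)
        stop("CFL violation at step %d: max |u| = %g exceeds 0.5", t, maxu);
      log_t.push_back((double)t);
      log_mass.push_back(mass);
      log_maxu.push_back(maxu);
      log_strain.push_back(max_strain);
      log_track.push_back(max_track);
      max_strain = 0.0;   // per-sample maxima
      max_track = 0.0;
      if (has_tr) {
        double mx = 0.0;
        for (int k = 0; k < tr_xu.size(); ++k) mx += tr_xu[k];
        log_trx.push_back(mx / tr_xu.size());
      }
      if (np > 0) {
        double my = 0.0;
        for (int pI = 0; pI < np; ++pI) {
          my += p_y[pI];
          if (isamp < nsamp) {
            log_part_y(pI, isamp) = p_y[pI];
            log_part_x(pI, isamp) = p_x[pI];
          }
        }
        log_py.push_back(my / np);
      }
      ++isamp;
    }
  }

  // --- pack state back ----------------------------------------------------
  List cilia_out(ncil);
  for (int c = 0; c < ncil; ++c) {
    int n = cx[c].size();
    NumericMatrix Xc(n, 2);
    for (int k = 0; k < n; ++k) { Xc(k, 0) = cx[c][k]; Xc(k, 1) = cy[c][k]; }
    cilia_out[c] = Xc;
  }
  List st = List::create(
    _["g"] = g, _["rho"] = rho, _["ux"] = ux, _["uy"] = uy,
    _["tau"] = tau, _["ind"] = ind, _["etaE"] = etaE,
    _["sxx"] = sxx, _["sxy"] = sxy, _["syy"] = syy,
    _["mem_x"] = has_mem ? (RObject)mem_x : (RObject)R_NilValue,
    _["mem_y"] = has_mem ? (RObject)mem_y : (RObject)R_NilValue,
    _["cilia"] = cilia_out,
    _["tr_x"] = has_tr ? (RObject)tr_x : (RObject)R_NilValue,
    _["tr_y"] = has_tr ? (RObject)tr_y : (RObject)R_NilValue,
    _["tr_xu"] = has_tr ? (RObject)tr_xu : (RObject)R_NilValue,
    _["t"] = t);
  st["p_x"] = (np > 0) ? (RObject)p_x : (RObject)R_NilValue;
  st["p_y"] = (np > 0) ? (RObject)p_y : (RObject)R_NilValue;
  st["p_ux"] = (np > 0) ? (RObject)p_ux : (RObject)R_NilValue;
  st["p_uy"] = (np > 0) ? (RObject)p_uy : (RObject)R_NilValue;
  st["p_om"] = (np > 0) ? (RObject)p_om : (RObject)R_NilValue;
  st["p_ang"] = (np > 0) ? (RObject)p_ang : (RObject)R_NilValue;

  List logs = List::create(
    _["t"] = wrap(log_t),
    _["tracer_mean_x"] = wrap(log_trx),
    _["particle_mean_y"] = wrap(log_py),
    _["particle_y"] = log_part_y,
    _["particle_x"] = log_part_x,
    _["mass"] = wrap(log_mass),
    _["max_speed"] = wrap(log_maxu),
    _["max_strain"] = wrap(log_strain),
    _["max_track_err"] = wrap(log_track));
  return List::create(_["state"] = st, _["logs"] = logs);
}
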