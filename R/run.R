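#' Assemble the initial simulation state
#'
#' Membrane: flat closed chain at the PCL depth. Cilia: initialized on their
#' virtual-cilium postures at t = 0 (no startup snap). Fluid: uniform density
#' at rest. Tracers: evenly spaced in x at mid-ML height with a small seeded
#' jitter. Particles (optional): evenly spaced in x at the requested height.
#'
#' @param cfg an [mcc_config()].
#' @param waveform optional [default_beat_generator()] result; built from the
#'   config when \code{NULL}.
#' @return List with \code{state} and \code{engine_cfg}, ready for
#'   [run_mcc()].
#' @keywords internal
#' @export
build_mcc_state <- function(cfg, waveform = NULL) {
  nx <- cfg$nx; ny <- cfg$ny
  if (is.null(waveform))
    waveform <- default_beat_generator(
      n_nodes = cfg$n_nodes, L = cfg$L, amplitude = cfg$beat_amplitude,
      asymmetry = cfg$beat_asymmetry, wave_width = cfg$beat_wave_width,
      recline = cfg$beat_recline, frequency = cfg$freq_hz)
  mem_x <- as.numeric(seq_len(nx) - 1)
  mem_y <- rep(cfg$pcl_lat, nx)
  lm0 <- update_layer_map(list(x = mem_x, y = mem_y), nx, ny,
                          cfg$nu_pcl, cfg$nu_mln, cfg$etaE_ml)
  cilia <- lapply(seq_len(cfg$n_cilia), function(k) {
    P <- beat_posture(waveform, cfg$phase_off[k])
    P[, 1] <- P[, 1] + cfg$roots[k]
    P
  })
  rho <- matrix(1, nx, ny)
  u0 <- matrix(0, nx, ny)
  set.seed(cfg$seed)
  spacing_tr <- nx / cfg$n_tracers
  tr_x <- (seq_len(cfg$n_tracers) - 0.5) * spacing_tr +
    runif(cfg$n_tracers, -0.2, 0.2) * spacing_tr
  tr_x <- tr_x %% nx
  tr_y <- rep(cfg$pcl_lat + 0.5 * cfg$ml_thickness_um / cfg$dx_um, cfg$n_tracers)
  state <- list(
    g = cf_equilibrium(rho, u0, u0), rho = rho, ux = u0, uy = u0,
    tau = lm0$tau, ind = lm0$indicator, etaE = lm0$eta_E,
    sxx = matrix(0, nx, ny), sxy = matrix(0, nx, ny),
    syy = matrix(0, nx, ny),
    mem_x = mem_x, mem_y = mem_y, cilia = cilia,
    tr_x = tr_x, tr_y = tr_y, tr_xu = tr_x, t = 0L)
  engine_cfg <- list(
    nx = nx, ny = ny,
    bc = c(.bc_codes[["noslip"]], .bc_codes[["slip_nee"]],
           .bc_codes[["periodic"]], .bc_codes[["periodic"]]),
    kernel = 4L, ds = cfg$ds, mem_ds = 1,
    two_layer = TRUE, use_stress = TRUE, stress_kappa = 0.005,
    lambda = cfg$lambda, nu_pcl = cfg$nu_pcl, nu_mln = cfg$nu_mln,
    etaE_ml = cfg$etaE_ml, ind_hw = 0.2 / cfg$dx_um,
    steps_per_T = as.numeric(cfg$steps_per_T),
    sample_every = as.integer(cfg$steps_per_T / cfg$sample_per_T),
    ks = cfg$ks, kb = cfg$kb, ksl = cfg$ksl,
    mem_ks = cfg$mem_ks, mem_kb = cfg$mem_kb, mem_y0 = cfg$pcl_lat,
    mem_rest = 0.75, fc_max = 1.0,
    beat_table = waveform$table, roots = cfg$roots,
    phase_off = cfg$phase_off)
  if (!is.null(cfg$particles)) {
    p <- cfg$particles
    pr <- 0.5 * p$diameter_um / cfg$dx_um
    seeded <- seed_particles(p$n, 2 * pr, p$y0_um / cfg$dx_um, nx)
    state$p_x <- seeded$x; state$p_y <- seeded$y
    state$p_ux <- numeric(p$n); state$p_uy <- numeric(p$n)
    state$p_om <- numeric(p$n); state$p_ang <- numeric(p$n)
    ns <- max(8L, as.integer(ceiling(2 * pi * pr)))
    m <- pi * pr^2                       # rho_f = 1, neutrally buoyant
    engine_cfg$particle_radius <- pr
    engine_cfg$particle_ns <- ns
    engine_cfg$particle_mass <- m
    engine_cfg$particle_inertia <- 0.5 * m * pr^2
    engine_cfg$particle_gamma <- if (is.null(p$gamma)) 0.2 else p$gamma
    engine_cfg$rep_C <- if (is.null(p$rep_C)) 1 else p$rep_C
    engine_cfg$rep_dcut <- if (is.null(p$rep_dcut)) 2 else p$rep_dcut
    engine_cfg$particle_grav <-
      if (is.null(p$grav)) 0 else p$grav   # (rho_p - rho_f) V_p g, y-component
  }
  list(state = state, engine_cfg = engine_cfg, waveform = waveform)
}

#' Run a mucociliary-clearance simulation
#'
#' Executes the composed model for \code{cfg$duration_T} beat periods and
#' post-processes the transport measurement: per-period tracer velocities,
#' developed-flow detection, and the mean ML velocity over the final 3T
#' window in um/s. Deterministic for a fixed config and seed.
#'
#' @param cfg an [mcc_config()].
#' @param waveform optional beat waveform override.
#' @param keep_state keep the final lattice/Lagrangian state (larger object).
#' @return An \code{mcc_run}: list with \code{config}, \code{samples}
#'   (data.frame of sampled diagnostics), \code{per_period_v} (lattice
#'   units), \code{warmup_T}, \code{v_ml_um_s}, \code{max_strain_pct},
#'   \code{max_track_err_L}, \code{particle_y_um} (matrix, um) and
#'   \code{particle_t_T} when particles are present, and optionally
#'   \code{state}.
#' @export
run_mcc <- function(cfg, waveform = NULL, keep_state = FALSE) {
  built <- build_mcc_state(cfg, waveform)
  state <- built$state
  ecfg <- built$engine_cfg
  nsteps <- as.integer(cfg$duration_T * cfg$steps_per_T)
  out <- cf_engine_run(state, ecfg, nsteps)
  state <- out$state
  logs <- out$logs
  samples <- data.frame(t = logs$t, t_T = logs$t / cfg$steps_per_T,
                        tracer_mean_x = logs$tracer_mean_x,
                        mass = logs$mass, max_speed = logs$max_speed,
                        max_strain = logs$max_strain,
                        max_track = logs$max_track_err)
  # per-period mean tracer velocity (lattice units / step)
  tT <- samples$t_T
  xbar <- samples$tracer_mean_x
  nper <- floor(max(tT))
  per_v <- vapply(seq_len(nper), function(p) {
    i0 <- which.min(abs(tT - (p - 1)))
    i1 <- which.min(abs(tT - p))
    (xbar[i1] - xbar[i0]) / (samples$t[i1] - samples$t[i0])
  }, numeric(1))
  warmup <- detect_developed_flow(per_v, fallback = max(1, nper - 3))
  v_ml <- mean_ml_velocity(samples$t, xbar, cfg$steps_per_T,
                           window_T = 3, warmup_T = min(warmup, nper - 3),
                           vel_unit_um_s = cfg$vel_unit_um_s)
  # strain bound over a developed beat: maximum over the final full period
  last_beat <- samples$t_T > max(samples$t_T) - 1
  run <- list(config = cfg, samples = samples, per_period_v = per_v,
              warmup_T = warmup, v_ml_um_s = v_ml,
              max_strain_pct = 100 * max(samples$max_strain[last_beat]),
              startup_strain_pct = 100 * max(samples$max_strain),
              max_track_err_L = max(samples$max_track[last_beat]) / cfg$L)
  if (!is.null(cfg$particles)) {
    run$particle_t_T <- logs$t / cfg$steps_per_T
    run$particle_y_um <- logs$particle_y * cfg$dx_um
    run$particle_mean_y_um <- logs$particle_mean_y * cfg$dx_um
  }
  if (keep_state) run$state <- state
  class(run) <- "mcc_run"
  run
}

#' @export
print.mcc_run <- function(x, ...) {
  cat("<mcc_run> ", x$config$duration_T, "T at spacing ",
      format(x$config$spacing_L, digits = 3), "L, phase diff ",
      x$config$phase_diff_T, "T\n  mean ML velocity ",
      format(x$v_ml_um_s, digits = 4), " um/s (warmup ", x$warmup_T,
      "T)\n  max cilium segment strain ",
      format(x$max_strain_pct, digits = 3), "%\n", sep = "")
  invisible(x)
}

#' Analytic Poiseuille velocity profile
#'
#' \code{u_x(y) = 4 u_max y (Ly - y) / Ly^2} for a planar channel with
#' no-slip walls at \code{y = 0} and \code{y = Ly}.
#'
#' @param y wall-normal coordinate(s), \code{0 <= y <= Ly}.
#' @param umax centerline velocity.
#' @param Ly channel height.
#' @export
analytic_u <- function(y, umax, Ly) 4 * umax * (y * Ly - y^2) / Ly^2

#' Analytic streamwise conformation profile
#'
#' Steady Oldroyd-B Poiseuille flow:
#' \code{A_xx(y) = 1 + 32 lambda^2 umax^2 (Ly - 2 y)^2 / Ly^4}, the
#' conformation-tensor component \code{A = I + (lambda/eta_E) sigma_E}.
#'
#' @param y wall-normal coordinate(s).
#' @param umax centerline velocity.
#' @param Ly channel height.
#' @param lambda elastic relaxation time.
#' @export
analytic_Axx <- function(y, umax, Ly, lambda)
  1 + 32 * lambda^2 * umax^2 * (Ly - 2 * y)^2 / Ly^4

#' Viscoelastic Poiseuille validation benchmark
#'
#' Runs the coupled LBM + Oldroyd-B solver in a planar channel with an
#' imposed parabolic inlet (non-equilibrium extrapolation), a zero-gradient
#' outflow, and NEE no-slip walls, to steady state; compares the mid-channel
#' velocity and conformation \code{A_xx} profiles with the closed forms
#' [analytic_u()] and [analytic_Axx()]. The Weissenberg number is defined as
#' \code{We = lambda umax / Ly}.
#'
#' @param We Weissenberg number.
#' @param nx,ny grid (walls at the first/last y-node).
#' @param umax inlet centerline velocity.
#' @param Re Reynolds number \code{umax Ly / nu_total}.
#' @param Rv solvent fraction of the total viscosity.
#' @param max_steps step budget for reaching steady state.
#' @param check_every residual check interval (steps).
#' @param tol steady-state criterion: max relative change of \code{u_x}
#'   per check interval.
#' @param stress_kappa artificial stress-diffusion coefficient stabilizing
#'   the explicit transport at high Weissenberg number.
#' @return A \code{poiseuille_bench}: profiles, relative L2/Linf errors for
#'   \code{u} and \code{A_xx}, steps used, residual history.
#' @export
run_poiseuille <- function(We = 0.01, nx = 120, ny = 40, umax = 0.1,
                           Re = 4, Rv = 0.9, max_steps = 60000,
                           check_every = 500, tol = 1e-8,
                           stress_kappa = 0.005) {
  Ly <- ny - 1
  nu_tot <- umax * Ly / Re
  nu_N <- Rv * nu_tot
  etaE <- (1 - Rv) * nu_tot
  lambda <- We * Ly / umax
  y <- seq_len(ny) - 1
  prof <- analytic_u(y, umax, Ly)
  rho <- matrix(1, nx, ny)
  ux0 <- matrix(prof, nx, ny, byrow = TRUE)
  uy0 <- matrix(0, nx, ny)
  # start from the developed analytic state (velocity parabola + steady UCM
  # stress); the solver must hold it as a fixed point. A zero-stress start
  # would need ~ lambda umax relaxation lengths of channel to develop.
  gdot <- 4 * umax * (Ly - 2 * y) / Ly^2
  sxy0 <- matrix(etaE * gdot, nx, ny, byrow = TRUE)
  sxx0 <- matrix(2 * etaE * lambda * gdot^2, nx, ny, byrow = TRUE)
  state <- list(
    g = cf_equilibrium(rho, ux0, uy0), rho = rho, ux = ux0, uy = uy0,
    tau = matrix(3 * nu_N + 0.5, nx, ny), ind = matrix(1, nx, ny),
    etaE = matrix(etaE, nx, ny),
    sxx = sxx0, sxy = sxy0,
    syy = matrix(0, nx, ny), t = 0L)
  ecfg <- list(
    nx = nx, ny = ny,
    bc = c(.bc_codes[["noslip_nee"]], .bc_codes[["noslip_nee"]],
           .bc_codes[["inlet"]], .bc_codes[["outflow"]]),
    inlet_ux = prof,
    inlet_sxx = 2 * etaE * lambda * gdot^2,
    inlet_sxy = etaE * gdot,
    inlet_syy = numeric(ny),
    kernel = 4L, ds = 1, two_layer = FALSE, use_stress = TRUE,
    lambda = lambda, nu_pcl = nu_N, nu_mln = nu_N, etaE_ml = etaE,
    ind_hw = 2, steps_per_T = 1, sample_every = as.integer(check_every),
    stress_kappa = stress_kappa,
    ks = 0, kb = 0, ksl = 0)
  steps <- 0
  resid <- numeric(0)
  u_prev <- state$ux
  while (steps < max_steps) {
    out <- cf_engine_run(state, ecfg, as.integer(check_every))
    state <- out$state
    steps <- steps + check_every
    r <- max(abs(state$ux - u_prev)) / max(abs(state$ux))
    resid <- c(resid, r)
    u_prev <- state$ux
    if (r < tol) break
  }
  mid <- round(nx / 2)
  u_num <- state$ux[mid, ]
  Axx_num <- 1 + (lambda / etaE) * state$sxx[mid, ]
  u_ref <- analytic_u(y, umax, Ly)
  A_ref <- analytic_Axx(y, umax, Ly, lambda)
  l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))
  linf <- function(a, b) max(abs(a - b)) / max(abs(b))
  structure(list(
    We = We, lambda = lambda, umax = umax, Ly = Ly, Rv = Rv, Re = Re,
    steps = steps, residual = resid,
    y = y, u_num = u_num, u_ref = u_ref, Axx_num = Axx_num, Axx_ref = A_ref,
    err_u_l2 = l2(u_num, u_ref), err_u_linf = linf(u_num, u_ref),
    err_Axx_l2 = l2(Axx_num, A_ref),
    err_Axx_linf = linf(Axx_num, A_ref)),
    class = "poiseuille_bench")
}

#' @export
print.poiseuille_bench <- function(x, ...) {
  cat("<poiseuille_bench> We = ", x$We, ", ", x$steps, " steps\n",
      "  u:   L2 ", format(x$err_u_l2, digits = 3), ", Linf ",
      format(x$err_u_linf, digits = 3), "\n",
      "  Axx: L2 ", format(x$err_Axx_l2, digits = 3), ", Linf ",
      format(x$err_Axx_linf, digits = 3), "\n", sep = "")
  invisible(x)
}
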