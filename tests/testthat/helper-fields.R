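# Shared builders for small lattice states used across test files.

# Minimal engine state for a quiescent fluid with optional stress fields.
quiet_state <- function(nx, ny, tau = 1) {
  z <- matrix(0, nx, ny)
  list(g = ciliaflow:::cf_equilibrium(matrix(1, nx, ny), z, z),
       rho = matrix(1, nx, ny), ux = z, uy = z,
       tau = matrix(tau, nx, ny), ind = matrix(1, nx, ny),
       etaE = z, sxx = z, sxy = z, syy = z, t = 0L)
}

# Engine config skeleton for fluid-only runs.
fluid_engine_cfg <- function(nx, ny, bc = c(0L, 0L, 0L, 0L), ...) {
  modifyList(list(nx = nx, ny = ny, bc = bc, kernel = 4L, ds = 1,
                  two_layer = FALSE, use_stress = FALSE, lambda = 1,
                  nu_pcl = 1 / 6, nu_mln = 1 / 6, etaE_ml = 0, ind_hw = 2,
                  steps_per_T = 1, sample_every = 1000L,
                  ks = 0, kb = 0, ksl = 0),
             list(...))
}

d2q9_e <- cbind(c(0, 1, 0, -1, 0, 1, -1, -1, 1),
                c(0, 0, 1, 0, -1, 1, 1, -1, -1))
d2q9_w <- c(4 / 9, rep(1 / 9, 4), rep(1 / 36, 4))
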