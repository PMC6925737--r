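#' Strain-rate tensor
#'
#' \code{D = (grad u + grad u^T)/2} by centered differences (one-sided at the
#' y-walls, wrapped across periodic edges). The trace is returned as an
#' incompressibility diagnostic.
#'
#' @param ux,uy velocity component matrices.
#' @param xper,yper periodic in x / y?
#' @return List with matrices \code{Dxx}, \code{Dxy}, \code{Dyy},
#'   \code{trace}, plus the full velocity gradient \code{Lxx}, \code{Lxy}
#'   (= dux/dy), \code{Lyx}, \code{Lyy}.
#' @export
strain_rate <- function(ux, uy, xper = TRUE, yper = FALSE) {
  L <- cf_velocity_gradient(ux, uy, xper, yper)
  list(Dxx = L$Lxx, Dxy = 0.5 * (L$Lxy + L$Lyx), Dyy = L$Lyy,
       trace = L$Lxx + L$Lyy,
       Lxx = L$Lxx, Lxy = L$Lxy, Lyx = L$Lyx, Lyy = L$Lyy)
}

#' Newtonian (solvent) stress
#'
#' \code{sigma_N = 2 eta_N D}, with a possibly node-dependent solvent
#' viscosity.
#'
#' @param D list with \code{Dxx}, \code{Dxy}, \code{Dyy} (from
#'   [strain_rate()]).
#' @param eta_n solvent dynamic viscosity: scalar or matrix.
#' @return List of stress component matrices.
#' @export
newtonian_stress <- function(D, eta_n) {
  list(sxx = 2 * eta_n * D$Dxx, sxy = 2 * eta_n * D$Dxy,
       syy = 2 * eta_n * D$Dyy)
}

#' Advance the Oldroyd-B elastic stress
#'
#' One or more explicit steps of the upper-convected Maxwell transport
#' equation
#' \code{ds/dt = -(u.grad)s + (grad u) s + s (grad u)^T + (2 eta_E D - s)/lambda},
#' with first-order upwind advection. \code{eta_E} may vary per node (zero in
#' the Newtonian layer); symmetry of the stress holds by construction (the
#' off-diagonal component is stored once).
#'
#' @param stress list with matrices \code{sxx}, \code{sxy}, \code{syy}.
#' @param ux,uy velocity fields.
#' @param eta_E elastic viscosity (scalar or matrix).
#' @param lambda relaxation time (time steps).
#' @param dt time step (lattice units).
#' @param nsteps number of steps (velocity held fixed).
#' @param xper periodic in x?
#' @param kappa artificial stress-diffusion coefficient (lattice units);
#'   small values stabilize the explicit transport at high Weissenberg
#'   number (0 disables).
#' @return Updated stress list.
#' @export
advance_elastic_stress <- function(stress, ux, uy, eta_E, lambda, dt = 1,
                                   nsteps = 1, xper = TRUE, kappa = 0) {
  if (max(abs(ux), abs(uy)) * dt >= 1)
    stop("advance_elastic_stress: CFL violation, max |u| dt >= dx")
  if (!is.matrix(eta_E)) eta_E <- matrix(eta_E, nrow(ux), ncol(ux))
  cf_stress_advance(stress$sxx, stress$sxy, stress$syy, ux, uy, eta_E,
                    lambda, dt, xper, as.integer(nsteps), kappa)
}

#' Elastic body-force density
#'
#' \code{f = div(ind * sigma_E)} by centered differences, tapered to zero
#' where the layer indicator vanishes; this is the force the mucus layer's
#' elastic stress exerts on the momentum equation.
#'
#' @param stress list with \code{sxx}, \code{sxy}, \code{syy}.
#' @param indicator layer indicator matrix in [0, 1] (1 = viscoelastic
#'   layer); defaults to 1 everywhere.
#' @param xper periodic in x?
#' @return List of matrices \code{fx}, \code{fy}.
#' @export
elastic_force_density <- function(stress, indicator = NULL, xper = TRUE) {
  if (is.null(indicator))
    indicator <- matrix(1, nrow(stress$sxx), ncol(stress$sxx))
  cf_stress_divergence(stress$sxx, stress$sxy, stress$syy, indicator, xper)
}

#' Two-layer map from the membrane position
#'
#' Builds the mucus-layer indicator (smoothed Heaviside of the signed height
#' above the membrane curve, transition half-width \code{hw}), the total
#' viscosity field (linear interpolation between the PCL and ML solvent
#' values across the band) and the relaxation-time field
#' \code{tau = 3 nu + 1/2}.
#'
#' @param membrane a [fiber()] with role \code{"membrane"} (closed chain,
#'   x-monotone), or a list with \code{x} (unwrapped, strictly increasing)
#'   and \code{y}.
#' @param nx,ny lattice size.
#' @param nu_pcl PCL kinematic viscosity (lattice units).
#' @param nu_ml_solvent ML solvent (Newtonian part) viscosity.
#' @param eta_E_ml ML elastic viscosity.
#' @param hw indicator transition half-width (lattice units).
#' @return A \code{layer_map}: list with \code{indicator}, \code{viscosity},
#'   \code{tau}, \code{eta_E}, \code{height} (membrane height per column).
#' @export
update_layer_map <- function(membrane, nx, ny, nu_pcl, nu_ml_solvent,
                             eta_E_ml = 0, hw = 2) {
  if (inherits(membrane, "fiber")) {
    mx <- membrane$X[, 1]; my <- membrane$X[, 2]
  } else {
    mx <- membrane$x; my <- membrane$y
  }
  h <- cf_membrane_height(mx, my, as.integer(nx))
  ind <- cf_layer_indicator(h, as.integer(ny), hw)
  nu <- nu_pcl + (nu_ml_solvent - nu_pcl) * ind
  structure(list(indicator = ind, viscosity = nu, tau = 3 * nu + 0.5,
                 eta_E = eta_E_ml * ind, height = h),
            class = "layer_map")
}
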