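#' D2Q9 lattice specification
#'
#' Bundles the discrete velocity set, quadrature weights and derived sound
#' speed of the D2Q9 lattice. Lattice units are used internally
#' (\code{dx = dt = 1} by default); one lattice length corresponds to a
#' configurable physical spacing (0.1 um at full resolution).
#'
#' @param nx,ny lattice node counts (>= 3).
#' @param dx lattice spacing.
#' @param dt time step.
#' @return An object of class \code{lattice_spec} with elements \code{e}
#'   (9 x 2 integer velocity matrix), \code{w} (weights), \code{cs}
#'   (sound speed \code{dx/(sqrt(3) dt)}), \code{nx}, \code{ny}, \code{dx},
#'   \code{dt}.
#' @examples
#' sp <- lattice_spec(10, 10)
#' sum(sp$w)            # 1
#' colSums(sp$w * sp$e) # zero vector
#' @export
lattice_spec <- function(nx, ny, dx = 1, dt = 1) {
  stopifnot(nx >= 3, ny >= 3, dx > 0, dt > 0)
  e <- cbind(c(0, 1, 0, -1, 0, 1, -1, -1, 1),
             c(0, 0, 1, 0, -1, 1, 1, -1, -1))
  w <- c(4 / 9, rep(1 / 9, 4), rep(1 / 36, 4))
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx, dt = dt,
                 cs = dx / (sqrt(3) * dt), e = e, w = w),
            class = "lattice_spec")
}

#' Equilibrium distribution functions
#'
#' Second-order Maxwell-Boltzmann expansion
#' \code{g_i^eq = w_i rho (1 + e.u/cs^2 + (e.u)^2/(2 cs^4) - u.u/(2 cs^2))}.
#'
#' @param rho density: scalar or \code{nx x ny} matrix (> 0).
#' @param u velocity: length-2 vector, or list \code{(ux, uy)} of matrices.
#' @param spec a [lattice_spec()]; defaults to a minimal spec for scalar use.
#' @return For scalar input a length-9 vector; for field input an
#'   \code{nx x ny x 9} array.
#' @export
lbm_equilibrium <- function(rho, u, spec = NULL) {
  if (is.matrix(rho)) {
    stopifnot(is.list(u))
    ux <- u[[1]]; uy <- u[[2]]
  } else {
    stopifnot(length(u) == 2)
    ux <- matrix(u[1], 1, 1); uy <- matrix(u[2], 1, 1)
    rho <- matrix(rho, 1, 1)
  }
  if (any(!is.finite(rho)) || any(!is.finite(ux)) || any(!is.finite(uy)))
    stop("lbm_equilibrium: non-finite density or velocity")
  if (any(rho <= 0)) stop("lbm_equilibrium: density must be positive")
  g <- cf_equilibrium(rho, ux, uy)
  if (length(rho) == 1L) as.vector(g) else g
}

#' Guo body-force source term
#'
#' \code{G_i = (1 - 1/(2 tau)) w_i [(e - u)/cs^2 + (e.u) e/cs^4] . f}. The
#' \code{(1 - 1/(2 tau))} prefactor pairs with the half-force velocity
#' correction applied in [lbm_macroscopic()].
#'
#' @param u velocity (length-2 vector or list of matrices).
#' @param f body-force density, same shape as \code{u}.
#' @param tau nondimensional relaxation time (> 0.5).
#' @param spec optional [lattice_spec()].
#' @return Length-9 vector or \code{nx x ny x 9} array.
#' @export
lbm_guo_source <- function(u, f, tau, spec = NULL) {
  if (tau <= 0.5)
    stop("lbm_guo_source: tau must exceed 0.5 (viscosity would be unstable)")
  if (is.list(u)) {
    G <- cf_guo_source(u[[1]], u[[2]], f[[1]], f[[2]], tau)
    G
  } else {
    G <- cf_guo_source(matrix(u[1], 1, 1), matrix(u[2], 1, 1),
                       matrix(f[1], 1, 1), matrix(f[2], 1, 1), tau)
    as.vector(G)
  }
}

#' Macroscopic moments with half-force correction
#'
#' \code{rho = sum_i g_i}; \code{u = (sum_i g_i e_i + f dt / 2) / rho};
#' \code{p = cs^2 rho}.
#'
#' @param g distribution array \code{nx x ny x 9} (or length-9 vector).
#' @param f body-force density: list \code{(fx, fy)} of matrices or length-2
#'   vector; defaults to zero.
#' @return List with \code{rho}, \code{ux}, \code{uy}, \code{p}.
#' @export
lbm_macroscopic <- function(g, f = NULL) {
  if (is.null(dim(g))) g <- array(g, c(1, 1, 9))
  nx <- dim(g)[1]; ny <- dim(g)[2]
  if (is.null(f)) f <- list(matrix(0, nx, ny), matrix(0, nx, ny))
  if (!is.list(f)) f <- list(matrix(f[1], nx, ny), matrix(f[2], nx, ny))
  m <- cf_macroscopic(g, f[[1]], f[[2]])
  if (any(m$rho <= 0)) stop("lbm_macroscopic: non-positive density (blow-up)")
  m$p <- m$rho / 3
  m
}

#' Create a fluid field
#'
#' Initializes a D2Q9 distribution field at equilibrium with the given
#' density/velocity, plus per-edge boundary conditions.
#'
#' @param nx,ny lattice size.
#' @param tau relaxation time: scalar or \code{nx x ny} matrix (> 0.5).
#' @param rho0 initial density (scalar or matrix).
#' @param u0 initial velocity: length-2 vector or list \code{(ux, uy)}.
#' @param bc named list/character with entries \code{bottom}, \code{top},
#'   \code{left}, \code{right}; each one of \code{"periodic"},
#'   \code{"noslip"} (halfway bounce-back), \code{"slip"} (specular),
#'   \code{"noslip_nee"} (non-equilibrium extrapolation wall),
#'   \code{"inlet"} (NEE with imposed profile), \code{"outflow"}
#'   (NEE, zero gradient).
#' @param inlet_ux optional length-\code{ny} imposed inlet x-velocity profile.
#' @return A \code{fluid_field} object (list).
#' @export
fluid_field <- function(nx, ny, tau = 1, rho0 = 1, u0 = c(0, 0),
                        bc = list(bottom = "periodic", top = "periodic",
                                  left = "periodic", right = "periodic"),
                        inlet_ux = NULL) {
  stopifnot(nx >= 3, ny >= 3)
  if (!is.matrix(rho0)) rho0 <- matrix(rho0, nx, ny)
  if (!is.list(u0)) u0 <- list(matrix(u0[1], nx, ny), matrix(u0[2], nx, ny))
  if (!is.matrix(tau)) tau <- matrix(tau, nx, ny)
  if (any(tau <= 0.5)) stop("fluid_field: tau must exceed 0.5 everywhere")
  bcv <- vapply(c("bottom", "top", "left", "right"),
                function(k) .bc_code(bc[[k]]), integer(1))
  x_nee <- bcv[3] >= 3 || bcv[4] >= 3
  y_nee <- bcv[1] >= 3 || bcv[2] >= 3
  if (xor(bcv[3] == 0, bcv[4] == 0) && !x_nee)
    stop("fluid_field: inconsistent x-edge assignment (periodic must pair)")
  if (xor(bcv[1] == 0, bcv[2] == 0) && !(y_nee || bcv[1] >= 1))
    stop("fluid_field: inconsistent y-edge assignment")
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), tau = tau,
    g = cf_equilibrium(rho0, u0[[1]], u0[[2]]),
    rho = rho0, ux = u0[[1]], uy = u0[[2]],
    fx = matrix(0, nx, ny), fy = matrix(0, nx, ny),
    bc = bcv,
    inlet_ux = if (is.null(inlet_ux)) numeric(ny) else inlet_ux
  ), class = "fluid_field")
}

#' Advance a fluid field
#'
#' Performs \code{nsteps} full lattice-Boltzmann updates: macroscopic moments,
#' BGK collision with Guo forcing, streaming with wall closure (halfway
#' bounce-back / specular / periodic), then non-equilibrium-extrapolation
#' edges where configured.
#'
#' @param field a [fluid_field()].
#' @param nsteps number of time steps.
#' @return The updated \code{fluid_field} with refreshed \code{g},
#'   \code{rho}, \code{ux}, \code{uy}.
#' @export
lbm_step <- function(field, nsteps = 1) {
  stopifnot(inherits(field, "fluid_field"))
  out <- cf_lbm_step(field$g, field$fx, field$fy, field$tau, field$bc,
                     field$inlet_ux, numeric(field$ny), as.integer(nsteps))
  field$g <- out$g
  field$rho <- out$rho
  field$ux <- out$ux
  field$uy <- out$uy
  field
}

#' @export
print.fluid_field <- function(x, ...) {
  cat("<fluid_field> ", x$nx, "x", x$ny,
      " | tau range [", format(min(x$tau), digits = 4), ", ",
      format(max(x$tau), digits = 4), "]",
      " | max |u| = ", format(max(sqrt(x$ux^2 + x$uy^2)), digits = 4),
      "\n", sep = "")
  invisible(x)
}
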