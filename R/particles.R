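#' Seed rigid particles
#'
#' Places \code{n} circular particles evenly spaced in x at height \code{y0},
#' with zero initial velocities. Rejects overlapping seeds and seeds that
#' would intersect the bottom wall.
#'
#' @param n particle count.
#' @param diameter particle diameter (lattice units).
#' @param y0 seeding height (lattice units).
#' @param nx channel length (lattice units).
#' @param spacing optional center spacing; defaults to \code{nx / n}.
#' @return List with vectors \code{x}, \code{y} and the scalar \code{radius}.
#' @export
seed_particles <- function(n, diameter, y0, nx, spacing = NULL) {
  r <- diameter / 2
  if (y0 < r) stop("seed_particles: particles would intersect the bottom wall")
  if (is.null(spacing)) spacing <- nx / n
  if (n > 1 && spacing <= diameter)
    stop("seed_particles: requested spacing overlaps adjacent particles")
  x <- if (n == 1) nx / 2 else (seq_len(n) - 0.5) * spacing
  list(x = x %% nx, y = rep(y0, n), radius = r)
}

#' Short-range repulsive force on a particle
#'
#' Stiff contact model \code{F = C ((d_cut - d)/d_cut)^2 n_hat} for surface
#' gaps \code{d < d_cut}, summed over three contact classes: other particles
#' (periodic minimum image in x), cilium nodes, and the two channel walls.
#' Interpenetration (\code{d < 0}) caps the magnitude at \code{C} with a
#' warning.
#'
#' @param xc,yc particle center.
#' @param radius particle radius.
#' @param others optional list with vectors \code{x}, \code{y} and scalar
#'   \code{radius} of the other particles.
#' @param fiber_nodes optional \code{m x 2} matrix of cilium node positions.
#' @param walls y-positions \code{c(bottom, top)} of the walls, or
#'   \code{NULL}.
#' @param nx channel period for the minimum image.
#' @param C force constant.
#' @param d_cut cutoff gap (lattice units).
#' @return Length-2 force vector.
#' @export
repulsive_force <- function(xc, yc, radius, others = NULL,
                            fiber_nodes = NULL, walls = NULL, nx = Inf,
                            C = 1, d_cut = 2) {
  f <- c(0, 0)
  push <- function(d, nhat) {
    if (d >= d_cut) return(c(0, 0))
    if (d < 0) {
      warning("repulsive_force: interpenetration (gap ", format(d), ")")
      d <- 0
    }
    C * ((d_cut - d) / d_cut)^2 * nhat
  }
  if (!is.null(others) && length(others$x)) {
    for (j in seq_along(others$x)) {
      dx <- xc - others$x[j]
      if (is.finite(nx)) dx <- dx - nx * round(dx / nx)
      dy <- yc - others$y[j]
      dist <- sqrt(dx^2 + dy^2)
      if (dist < 1e-12) next
      f <- f + push(dist - radius - others$radius, c(dx, dy) / dist)
    }
  }
  if (!is.null(fiber_nodes)) {
    fiber_nodes <- rbind(fiber_nodes)
    for (j in seq_len(nrow(fiber_nodes))) {
      dx <- xc - fiber_nodes[j, 1]
      if (is.finite(nx)) dx <- dx - nx * round(dx / nx)
      dy <- yc - fiber_nodes[j, 2]
      dist <- sqrt(dx^2 + dy^2)
      if (dist < 1e-12) next
      f <- f + push(dist - radius, c(dx, dy) / dist)
    }
  }
  if (!is.null(walls)) {
    f <- f + push(yc - radius - walls[1], c(0, 1))
    f <- f + push(walls[2] - (yc + radius), c(0, -1))
  }
  f
}

#' Penalty-coupling hydrodynamic force and torque
#'
#' Direct-forcing immersed-boundary estimate of the surface-traction
#' integral: the penalty force that pushes the interpolated fluid velocity
#' at each surface point toward the rigid-body velocity
#' \code{U_p + Omega x (X_s - X_c)} is spread to the fluid, and its negative
#' (with moments) is the reaction on the particle. This function evaluates
#' the reaction for a given fluid state without modifying it.
#'
#' @param xc,yc center; \code{up}, \code{vp} translational velocity;
#'   \code{om} angular velocity; \code{ang} phase of the surface points.
#' @param radius particle radius; \code{ns} surface point count.
#' @param ux,uy fluid velocity matrices.
#' @param gamma penalty coefficient (force per unit velocity mismatch per
#'   unit arclength).
#' @param kernel an [ib_kernel()].
#' @return List with \code{force} (length-2) and \code{torque} (scalar).
#' @export
hydrodynamic_force_torque <- function(xc, yc, up, vp, om, radius,
                                      ux, uy, ns = NULL, ang = 0,
                                      gamma = 0.2, kernel = ib_kernel()) {
  if (is.null(ns)) ns <- max(8L, as.integer(ceiling(2 * pi * radius)))
  ds_p <- 2 * pi * radius / ns
  th <- ang + 2 * pi * (seq_len(ns) - 1) / ns
  rx <- radius * cos(th); ry <- radius * sin(th)
  X <- cbind(xc + rx, yc + ry)
  U <- interpolate_velocity(ux, uy, X, kernel)
  urx <- up - om * ry
  ury <- vp + om * rx
  fx <- gamma * (urx - U[, 1])   # on the fluid
  fy <- gamma * (ury - U[, 2])
  list(force = c(-sum(fx), -sum(fy)) * ds_p,
       torque = -sum(rx * fy - ry * fx) * ds_p)
}

#' Explicit rigid-body update
#'
#' \code{U += F/m dt}; \code{Omega += T/I dt}; \code{X += U dt}. Surface
#' points are regenerated from center and angle, so the circle stays exact.
#'
#' @param p list with \code{x}, \code{y}, \code{ux}, \code{uy}, \code{om},
#'   \code{ang}, \code{mass}, \code{inertia}.
#' @param F force (length-2); \code{Tq} torque.
#' @param dt time step.
#' @return Updated particle list.
#' @export
advance_particle <- function(p, F, Tq, dt = 1) {
  p$ux <- p$ux + F[1] / p$mass * dt
  p$uy <- p$uy + F[2] / p$mass * dt
  p$om <- p$om + Tq / p$inertia * dt
  p$x <- p$x + p$ux * dt
  p$y <- p$y + p$uy * dt
  p$ang <- p$ang + p$om * dt
  p
}
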