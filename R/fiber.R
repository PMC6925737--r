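#' Node-spring fiber
#'
#' An ordered chain of Lagrangian nodes with extensional and bending
#' stiffness, used both for cilia (open, root-anchored) and for the dividing
#' membrane (closed periodic chain across the channel seam).
#'
#' @param X \code{n x 2} node coordinates (lattice units), \code{n >= 5}.
#' @param ks extensional coefficient (nondimensional; 2.0 default).
#' @param kb bending coefficient (1.0 default).
#' @param ds natural segment length.
#' @param role \code{"cilium"} or \code{"membrane"}; membranes never receive
#'   the virtual-spring driving force.
#' @param closed closed periodic chain? (membrane spanning the channel).
#' @param Lx channel period used to close the seam segment of a closed chain.
#' @param anchor index of a position-clamped node (1 = cilium root), or
#'   \code{NULL}.
#' @return A \code{fiber} object.
#' @export
fiber <- function(X, ks = 2, kb = 1, ds = 1, role = c("cilium", "membrane"),
                  closed = FALSE, Lx = NA_real_, anchor = NULL) {
  role <- match.arg(role)
  X <- as.matrix(X)
  if (nrow(X) < 5) stop("fiber: at least 5 nodes required")
  if (closed && is.na(Lx)) stop("fiber: closed chain needs the period Lx")
  seg <- if (closed) {
    dx <- diff(c(X[, 1], X[1, 1] + Lx)); dy <- diff(c(X[, 2], X[1, 2]))
    sqrt(dx^2 + dy^2)
  } else sqrt(diff(X[, 1])^2 + diff(X[, 2])^2)
  if (any(seg < 1e-12)) stop("fiber: coincident adjacent nodes")
  structure(list(X = X, ks = ks, kb = kb, ds = ds, role = role,
                 closed = closed, Lx = Lx, anchor = anchor),
            class = "fiber")
}

#' Stretching force
#'
#' Discrete divergence of the segment tension
#' \code{T_j = ks (|dX_j|/ds - 1)} along the unit tangent: Hookean
#' resistance to extension/compression of each segment. Internal forces sum
#' to zero (tension telescopes).
#'
#' @param fib a [fiber()].
#' @return \code{n x 2} matrix of nodal force densities.
#' @export
stretching_force <- function(fib) {
  stopifnot(inherits(fib, "fiber"))
  cf_fiber_stretch(fib$X, fib$ks, fib$ds, fib$closed,
                   if (is.na(fib$Lx)) 0 else fib$Lx)
}

#' Bending force
#'
#' Variational derivative of the discrete bending energy
#' \code{E = kb/2 int |d2X/ds2|^2 ds}, giving the restoring force
#' \code{-kb d4X/ds4}. For open fibers the natural boundary conditions are
#' the free-end moment and shear conditions \code{d2X/ds2 = d3X/ds3 = 0};
#' net force and torque vanish identically.
#'
#' @param fib a [fiber()].
#' @return \code{n x 2} matrix of nodal force densities.
#' @export
bending_force <- function(fib) {
  stopifnot(inherits(fib, "fiber"))
  cf_fiber_bend(fib$X, fib$kb, fib$ds, fib$closed,
                if (is.na(fib$Lx)) 0 else fib$Lx)
}

#' Virtual-cilium driving force
#'
#' Penalty springs connecting the actual cilium nodes X to the prescribed
#' virtual-cilium posture Y: \code{F_c = ksl (Y - X)} nodewise.
#'
#' @param fib a [fiber()] with role \code{"cilium"}.
#' @param Y \code{n x 2} virtual-cilium node positions.
#' @param ksl penalty spring coefficient (1.0 default).
#' @return \code{n x 2} matrix.
#' @export
driving_force <- function(fib, Y, ksl = 1) {
  stopifnot(inherits(fib, "fiber"))
  if (fib$role != "cilium")
    stop("driving_force: only cilia are driven by a virtual fiber")
  Y <- as.matrix(Y)
  if (!all(dim(Y) == dim(fib$X)))
    stop("driving_force: virtual fiber node count mismatch")
  ksl * (Y - fib$X)
}

#' Total fiber force
#'
#' Cilia: stretching + bending + driving; membrane: stretching + bending.
#' This is the Lagrangian force handed to [spread_force()].
#'
#' @param fib a [fiber()].
#' @param Y optional virtual-cilium posture (required for driven cilia).
#' @param ksl penalty coefficient.
#' @return \code{n x 2} matrix.
#' @export
total_fiber_force <- function(fib, Y = NULL, ksl = 1) {
  F <- stretching_force(fib) + bending_force(fib)
  if (fib$role == "cilium" && !is.null(Y)) F <- F + driving_force(fib, Y, ksl)
  F
}
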