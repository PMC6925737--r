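#' Regularized delta kernel
#'
#' 1D kernel factor used for immersed-boundary force spreading and velocity
#' interpolation. The default is the 4-point Peskin kernel (support half-width
#' 2); a 2-point hat kernel is available for tests. Both satisfy the discrete
#' partition of unity \code{sum_i phi(x - i) = 1} for any real \code{x}.
#'
#' @param kind \code{"peskin4"} or \code{"hat2"}.
#' @return An \code{ib_kernel} object with elements \code{kind} (integer code
#'   passed to the C++ core), \code{support} and \code{phi} (vectorized R
#'   evaluator).
#' @export
ib_kernel <- function(kind = c("peskin4", "hat2")) {
  kind <- match.arg(kind)
  code <- if (kind == "peskin4") 4L else 2L
  structure(list(kind = code,
                 support = if (code == 4L) 2 else 1,
                 phi = function(r) cf_ib_phi(as.numeric(r), code)),
            class = "ib_kernel")
}

#' Spread Lagrangian forces onto the lattice
#'
#' \code{f(x) = sum_s F(s) phi(x - X_s) phi(y - Y_s) ds}. Periodic in x; the
#' kernel is clipped at the y-walls (force landing beyond a wall is absorbed
#' by it). Points outside the domain in y are rejected.
#'
#' @param X \code{n x 2} Lagrangian positions (lattice units).
#' @param F \code{n x 2} Lagrangian forces (force density along the boundary).
#' @param nx,ny lattice size.
#' @param ds Lagrangian segment length (default 1).
#' @param kernel an [ib_kernel()].
#' @return List of \code{nx x ny} matrices \code{fx}, \code{fy}.
#' @export
spread_force <- function(X, F, nx, ny, ds = 1, kernel = ib_kernel()) {
  X <- rbind(X); F <- rbind(F)
  stopifnot(ncol(X) == 2, ncol(F) == 2, nrow(X) == nrow(F))
  cf_spread(X, F, as.integer(nx), as.integer(ny), ds, kernel$kind)
}

#' Interpolate lattice velocity at Lagrangian points
#'
#' \code{U(s) = sum_x u(x) phi(x - X_s) phi(y - Y_s)}; the adjoint of
#' [spread_force()] with respect to the discrete inner products.
#'
#' @param ux,uy \code{nx x ny} velocity component matrices.
#' @param X \code{n x 2} point positions.
#' @param kernel an [ib_kernel()].
#' @return \code{n x 2} matrix of interpolated velocities.
#' @export
interpolate_velocity <- function(ux, uy, X, kernel = ib_kernel()) {
  X <- rbind(X)
  cf_interp(ux, uy, X, kernel$kind)
}
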