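#' Analytic velocity-field fixtures
#'
#' Deterministic lattice velocity fields with closed-form derivatives, used
#' as oracles for the stencil and transport operators.
#'
#' Kinds: \code{"uniform"} (params \code{c}), \code{"shear"}
#' (\code{gammadot}; u_x = gammadot * y), \code{"poiseuille"} (\code{umax},
#' \code{Ly}; the parabolic channel profile), \code{"shear_wave"}
#' (\code{A}, \code{k_mode}; u_x = A sin(2 pi k y / ny)), \code{"random_smooth"}
#' (seeded low-order trigonometric series, params \code{seed},
#' \code{n_modes}, \code{A}).
#'
#' @param kind field type.
#' @param nx,ny lattice size.
#' @param params named list of kind-specific parameters.
#' @return List with \code{ux}, \code{uy} and (where available) closed-form
#'   derivative fields \code{dux_dy}, \code{D} etc.
#' @export
make_analytic_field <- function(kind = c("uniform", "shear", "poiseuille",
                                         "shear_wave", "random_smooth"),
                                nx, ny, params = list()) {
  kind <- match.arg(kind)
  y <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  x <- matrix(rep(0:(nx - 1), ny), nx, ny)
  zero <- matrix(0, nx, ny)
  switch(kind,
    uniform = {
      cc <- params$c %||% c(0.1, 0)
      list(ux = matrix(cc[1], nx, ny), uy = matrix(cc[2], nx, ny),
           dux_dy = zero)
    },
    shear = {
      g <- params$gammadot %||% 0.01
      list(ux = g * y, uy = zero, dux_dy = matrix(g, nx, ny),
           Dxy = matrix(g / 2, nx, ny))
    },
    poiseuille = {
      umax <- params$umax %||% 0.1
      Ly <- params$Ly %||% (ny - 1)
      list(ux = analytic_u(y, umax, Ly), uy = zero,
           dux_dy = 4 * umax * (Ly - 2 * y) / Ly^2)
    },
    shear_wave = {
      A <- params$A %||% 0.01
      k <- params$k_mode %||% 1
      kk <- 2 * pi * k / ny
      list(ux = A * sin(kk * y), uy = zero, dux_dy = A * kk * cos(kk * y),
           k_wave = kk)
    },
    random_smooth = {
      seed <- params$seed %||% 1
      nm <- params$n_modes %||% 3
      A <- params$A %||% 0.01
      set.seed(seed)
      ux <- zero; uy <- zero
      dux_dx <- zero; dux_dy <- zero; duy_dx <- zero; duy_dy <- zero
      for (m in seq_len(nm)) {
        kx <- 2 * pi * sample(1:3, 1) / nx
        ky <- 2 * pi * sample(1:3, 1) / ny
        a <- A * runif(4, -1, 1)
        ux <- ux + a[1] * sin(kx * x) * cos(ky * y)
        uy <- uy + a[2] * cos(kx * x) * sin(ky * y)
        dux_dx <- dux_dx + a[1] * kx * cos(kx * x) * cos(ky * y)
        dux_dy <- dux_dy - a[1] * ky * sin(kx * x) * sin(ky * y)
        duy_dx <- duy_dx - a[2] * kx * sin(kx * x) * sin(ky * y)
        duy_dy <- duy_dy + a[2] * ky * cos(kx * x) * cos(ky * y)
      }
      list(ux = ux, uy = uy, dux_dx = dux_dx, dux_dy = dux_dy,
           duy_dx = duy_dx, duy_dy = duy_dy)
    })
}

#' Fiber-shape fixtures
#'
#' Exact nodal coordinates with known analytic stretching/bending forces,
#' used as oracles for the elastic-structure operators.
#'
#' Kinds: \code{"straight"} (params \code{angle}, \code{strain}),
#' \code{"arc"} (quadratic arc \code{y = a x^2}, param \code{a}),
#' \code{"sinusoid"} (\code{X_y(s) = A sin(k s)}, params \code{A}, \code{k}).
#'
#' @param kind shape type.
#' @param n node count (>= 5).
#' @param ds segment rest length.
#' @param params named list of parameters.
#' @return List with \code{X} (n x 2) and the oracle values documented per
#'   kind (e.g. \code{bend_oracle_y} for the sinusoid interior).
#' @export
make_fiber_shape <- function(kind = c("straight", "arc", "sinusoid"),
                             n = 21, ds = 1, params = list()) {
  kind <- match.arg(kind)
  s <- (0:(n - 1)) * ds
  switch(kind,
    straight = {
      ang <- params$angle %||% (pi / 2)
      strain <- params$strain %||% 0
      d <- ds * (1 + strain)
      X <- cbind(s / ds * d * cos(ang), s / ds * d * sin(ang))
      list(X = X, strain = strain,
           end_tension = params$ks %||% 2 * strain)
    },
    arc = {
      a <- params$a %||% 0.01
      X <- cbind(s, a * s^2)
      list(X = X)
    },
    sinusoid = {
      A <- params$A %||% 0.5
      k <- params$k %||% (2 * pi / (n * ds / 3))
      X <- cbind(s, A * sin(k * s))
      list(X = X, A = A, k = k,
           # interior restoring force of -kb d4X/ds4 for X_y = A sin(ks)
           bend_oracle_y = function(kb) -kb * A * k^4 * sin(k * s))
    })
}

#' Synthetic per-period velocity logs
#'
#' Oracles for the developed-flow detector: \code{"constant"},
#' \code{"converging"} (exponential approach, param \code{rate}, converged
#' below tolerance after period \code{k}), \code{"oscillating"} (never
#' converges).
#'
#' @param kind log type.
#' @param n periods.
#' @param params named list (\code{v0}, \code{rate}, \code{amp}).
#' @return Numeric vector of per-period velocities.
#' @export
make_velocity_log <- function(kind = c("constant", "converging",
                                       "oscillating"),
                              n = 30, params = list()) {
  kind <- match.arg(kind)
  v0 <- params$v0 %||% 1
  switch(kind,
    constant = rep(v0, n),
    converging = v0 * (1 - (params$rate %||% 0.5)^(seq_len(n))),
    oscillating = v0 * (1 + (params$amp %||% 0.5) * (-1)^(seq_len(n))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
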