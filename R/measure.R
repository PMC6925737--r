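#' Mean mucus-layer transport velocity from tracers
#'
#' The mean velocity of the tracepoints over a 3T window after the flow has
#' developed: net unwrapped x-displacement of the tracer mean divided by the
#' window, converted to physical units.
#'
#' @param t sample times (steps).
#' @param tracer_mean_x mean unwrapped tracer x-position per sample (lattice
#'   units; unwrapping accumulates full channel lengths across the periodic
#'   seam).
#' @param steps_per_T steps per beat period.
#' @param window_T averaging window in beat periods (3 by default).
#' @param warmup_T window start (periods); the window is
#'   \code{[warmup_T, warmup_T + window_T]} clipped to the log.
#' @param vel_unit_um_s physical velocity per lattice velocity unit
#'   (\code{dx_um * freq_hz * steps_per_T}); 1 leaves lattice units.
#' @return Mean transport velocity (um/s when \code{vel_unit_um_s} is
#'   physical).
#' @export
mean_ml_velocity <- function(t, tracer_mean_x, steps_per_T, window_T = 3,
                             warmup_T = 0, vel_unit_um_s = 1) {
  stopifnot(length(t) == length(tracer_mean_x), length(t) >= 2)
  tT <- t / steps_per_T
  if (max(tT) < warmup_T + window_T)
    warmup_T <- max(0, max(tT) - window_T)
  i0 <- which.min(abs(tT - warmup_T))
  i1 <- which.min(abs(tT - (warmup_T + window_T)))
  if (i1 <= i0) stop("mean_ml_velocity: trajectory shorter than the window")
  v_lat <- (tracer_mean_x[i1] - tracer_mean_x[i0]) / (t[i1] - t[i0])
  v_lat * vel_unit_um_s
}

#' Detect developed flow
#'
#' Earliest beat period after which consecutive per-period mean velocities
#' differ by less than \code{tol} (relative). Falls back (with a warning) if
#' the log never converges.
#'
#' @param per_period_v per-period mean velocities.
#' @param tol relative change threshold (0.02).
#' @param fallback period returned when no convergence is found.
#' @return Warmup end period (integer).
#' @export
detect_developed_flow <- function(per_period_v, tol = 0.02,
                                  fallback = NULL) {
  n <- length(per_period_v)
  if (is.null(fallback)) fallback <- max(1, floor(2 * n / 3))
  if (n < 2) return(1L)
  for (p in 2:n) {
    denom <- max(abs(per_period_v[p]), 1e-300)
    if (abs(per_period_v[p] - per_period_v[p - 1]) / denom < tol)
      return(as.integer(p))
  }
  warning("detect_developed_flow: no convergence; using fallback period ",
          fallback)
  as.integer(fallback)
}

#' Mean particle height time series
#'
#' The mean y-coordinate over all particles per output sample, expressing the
#' overall migration trajectory.
#'
#' @param t_T sample times in beat periods.
#' @param particle_y \code{n_particles x n_samples} matrix of y-positions
#'   (lattice units or um).
#' @param dx_um conversion to um (1 if already physical).
#' @return data.frame with \code{t_T} and \code{y_um}.
#' @export
mean_particle_height <- function(t_T, particle_y, dx_um = 1) {
  stopifnot(ncol(particle_y) == length(t_T))
  data.frame(t_T = t_T, y_um = colMeans(particle_y) * dx_um)
}

#' First crossing of the cilia-tip region
#'
#' Time (in beat periods) at which the mean particle height first reaches
#' the top of the beating cilia (y >= cilium length), or \code{Inf} if it
#' never does ("confined").
#'
#' @param t_T sample times (periods).
#' @param mean_y_um mean particle height (um).
#' @param tip_um cilia-tip height (5.5 um).
#' @return Crossing time in T, or \code{Inf}.
#' @export
tip_crossing_time <- function(t_T, mean_y_um, tip_um = 5.5) {
  hit <- which(mean_y_um >= tip_um)
  if (!length(hit)) return(Inf)
  t_T[hit[1]]
}
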