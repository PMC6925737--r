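#' Build a mucociliary-clearance simulation configuration
#'
#' Collects the full parameterization of one run and derives every lattice
#' quantity from it. Physical anchors: 1 lattice unit = \code{dx_um}
#' micrometers, and one beat period T = \code{steps_per_T} time steps with a
#' beat frequency of \code{freq_hz} (so 1 step = \code{1/(freq_hz *
#' steps_per_T)} seconds). The default \code{"full"} resolution matches the
#' reference channel (600 x 102 nodes at 0.1 um); \code{"half"} runs the
#' same physics at 0.2 um per node, the reduced mode used for desk-scale
#' checks.
#'
#' The viscosity map: the PCL is Newtonian with lattice viscosity
#' \code{nu_pcl}; the ML total viscosity is \code{visc_ratio} times larger,
#' split into a solvent part \code{Rv} and an elastic part \code{1 - Rv}
#' carried by the Oldroyd-B stress with relaxation time
#' \code{lambda = We * T}. The nominal Reynolds number of the modelled flow
#' regime is creeping (Re = 0.05); the effective lattice Reynolds number
#' achieved under these numerical scales is reported in the configuration as
#' a diagnostic (see the methods vignette for the reasoning).
#'
#' @param resolution \code{"full"} (0.1 um/node) or \code{"half"}
#'   (0.2 um/node).
#' @param duration_T total simulated beat periods.
#' @param ml_thickness_um mucus-layer thickness (um); channel top (slip
#'   wall) sits at PCL depth + ML thickness.
#' @param pcl_depth_um periciliary-liquid depth (um).
#' @param spacing_L inter-cilium spacing in units of cilium length L.
#' @param phase_diff_T adjacent-cilium phase difference in beat periods.
#' @param enforce_closure snap the channel length so the metachronal phase
#'   pattern closes across the periodic seam (adjacent-cilium phase offsets
#'   wrap consistently). Without closure the seam pair beats with a large
#'   phase jump and neighboring cilia can collide.
#' @param channel_um target channel length (um).
#' @param beat_amplitude half-sweep angle (radians) of the effective stroke;
#'   the default is the calibrated value reproducing ~42 um/s mean ML
#'   velocity at spacing 0.55 L.
#' @param beat_asymmetry effective-stroke fraction of the cycle.
#' @param beat_wave_width recovery curvature-wave width (fraction of L).
#' @param beat_recline recovery reclining fraction (see
#'   [default_beat_generator()]).
#' @param We Weissenberg number; ML relaxation time is \code{lambda = We*T}.
#' @param visc_ratio ML : PCL total-viscosity ratio.
#' @param Rv ML solvent fraction \code{eta_MN / (eta_MN + eta_ME)}.
#' @param nu_pcl PCL kinematic viscosity in lattice units.
#' @param steps_per_T steps per beat period (\code{NULL}: resolution
#'   default).
#' @param freq_hz beat frequency (Hz).
#' @param ks,kb,ksl cilium extensional, bending and driving-spring
#'   coefficients in lattice force units (see the methods vignette for the
#'   mapping from the nondimensional values Ks = 2, Kb = 1, Ksl = 1).
#' @param mem_ks,mem_kb membrane extensional and bending coefficients.
#' @param n_tracers transport-measurement tracer count.
#' @param particles \code{NULL}, or a list with \code{n}, \code{diameter_um},
#'   \code{y0_um} describing the seeded rigid particles.
#' @param seed integer seed (tracer placement jitter).
#' @param sample_per_T measurement samples per beat period.
#' @return An object of class \code{mcc_config} (a list with the inputs plus
#'   all derived lattice quantities).
#' @export
mcc_config <- function(resolution = c("full", "half"),
                       duration_T = 30,
                       ml_thickness_um = 4,
                       pcl_depth_um = 6.2,
                       spacing_L = 0.55,
                       phase_diff_T = 0.02,
                       enforce_closure = TRUE,
                       channel_um = 60,
                       beat_amplitude = 0.6,
                       beat_asymmetry = 0.3,
                       beat_wave_width = 0.35,
                       beat_recline = 0.7,
                       We = 0.01,
                       visc_ratio = 40,
                       Rv = 0.975,
                       nu_pcl = 1,
                       steps_per_T = NULL,
                       freq_hz = 20,
                       ks = 8, kb = 0.25, ksl = 1,
                       mem_ks = 2, mem_kb = 1,
                       n_tracers = 50,
                       particles = NULL,
                       seed = 1L,
                       sample_per_T = 20) {
  resolution <- match.arg(resolution)
  if (ml_thickness_um <= 0) stop("mcc_config: ML thickness must be positive")
  if (pcl_depth_um <= 5.5)
    stop("mcc_config: PCL depth must exceed the cilium length (5.5 um)")
  if (duration_T <= 0) stop("mcc_config: duration must be positive")
  dx_um <- if (resolution == "full") 0.1 else 0.2
  if (is.null(steps_per_T))
    steps_per_T <- if (resolution == "full") 4000L else 2000L
  L <- 5.5 / dx_um                       # cilium length, lattice units
  n_nodes <- as.integer(round(L)) + 1L
  arr <- build_cilia_array(spacing_L, phase_diff_T, L,
                           nx_target = round(channel_um / dx_um),
                           enforce_closure = enforce_closure)
  nx <- arr$channel_length
  ny <- as.integer(round((pcl_depth_um + ml_thickness_um) / dx_um))
  pcl_lat <- pcl_depth_um / dx_um
  nu_ml_total <- visc_ratio * nu_pcl
  nu_mln <- Rv * nu_ml_total             # ML solvent part (via tau)
  etaE_ml <- (1 - Rv) * nu_ml_total      # ML elastic part (via stress)
  lambda <- We * steps_per_T
  vel_unit_um_s <- dx_um * freq_hz * steps_per_T
  u_tip <- 2 * beat_amplitude * L / (beat_asymmetry * steps_per_T)
  cfg <- list(
    resolution = resolution, dx_um = dx_um, steps_per_T = steps_per_T,
    duration_T = duration_T, freq_hz = freq_hz,
    ml_thickness_um = ml_thickness_um, pcl_depth_um = pcl_depth_um,
    channel_um = channel_um,
    spacing_L = arr$spacing_L, phase_diff_T = phase_diff_T,
    enforce_closure = enforce_closure,
    beat_amplitude = beat_amplitude, beat_asymmetry = beat_asymmetry,
    beat_wave_width = beat_wave_width, beat_recline = beat_recline,
    We = We, visc_ratio = visc_ratio, Rv = Rv, nu_pcl = nu_pcl,
    ks = ks, kb = kb, ksl = ksl, mem_ks = mem_ks, mem_kb = mem_kb,
    n_tracers = n_tracers, particles = particles,
    seed = as.integer(seed), sample_per_T = sample_per_T,
    # derived lattice quantities
    L = L, n_nodes = n_nodes, ds = L / (n_nodes - 1),
    nx = nx, ny = ny, pcl_lat = pcl_lat,
    n_cilia = arr$n_cilia, roots = arr$roots, phase_off = arr$phase_off,
    nu_mln = nu_mln, etaE_ml = etaE_ml, lambda = lambda,
    tau_pcl = 3 * nu_pcl + 0.5, tau_ml = 3 * nu_mln + 0.5,
    vel_unit_um_s = vel_unit_um_s,
    Re_nominal = 0.05,
    Re_effective = u_tip * L / nu_pcl,
    u_tip_est = u_tip)
  class(cfg) <- "mcc_config"
  cfg
}

#' @export
print.mcc_config <- function(x, ...) {
  cat("<mcc_config> ", x$nx, "x", x$ny, " lattice (", x$dx_um,
      " um/node), ", x$n_cilia, " cilia @ spacing ",
      format(x$spacing_L, digits = 3), "L, phase diff ", x$phase_diff_T,
      "T\n  T = ", x$steps_per_T, " steps, duration ", x$duration_T,
      "T; ML ", x$ml_thickness_um, " um / PCL ", x$pcl_depth_um, " um\n",
      "  tau: PCL ", format(x$tau_pcl, digits = 3), ", ML ",
      format(x$tau_ml, digits = 3), "; We ", x$We, " (lambda ", x$lambda,
      " steps); amplitude ", x$beat_amplitude, " rad\n",
      "  nominal Re ", x$Re_nominal, ", effective lattice Re ~ ",
      format(x$Re_effective, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write / read a configuration as YAML
#'
#' Serializes the input (non-derived) fields of an [mcc_config()]; reading
#' rebuilds the config so all derived lattice quantities are reconstructed.
#'
#' @param cfg an \code{mcc_config}.
#' @param file path to a YAML file.
#' @return \code{read_config} returns an \code{mcc_config}.
#' @export
write_config <- function(cfg, file) {
  keep <- c("resolution", "duration_T", "ml_thickness_um", "pcl_depth_um",
            "spacing_L", "phase_diff_T", "enforce_closure", "channel_um",
            "beat_amplitude", "beat_asymmetry", "beat_wave_width",
            "beat_recline", "We", "visc_ratio", "Rv",
            "nu_pcl", "steps_per_T", "freq_hz", "ks", "kb", "ksl",
            "mem_ks", "mem_kb",
            "n_tracers", "particles", "seed", "sample_per_T")
  yaml::write_yaml(cfg[keep], file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  v <- yaml::read_yaml(file)
  v <- v[!vapply(v, is.null, logical(1))]
  do.call(mcc_config, v)
}
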