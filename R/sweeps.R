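#' Mucus-thickness sweep
#'
#' One run per (ML thickness, cilium spacing) combination; reports the mean
#' ML velocity of each. Per-run failures are recorded as \code{NA} and the
#' sweep continues.
#'
#' @param base an [mcc_config()] supplying every non-swept parameter.
#' @param thickness_um ML thickness values (um).
#' @param spacing_L cilium spacings (units of L).
#' @return data.frame with \code{ml_thickness_um}, \code{spacing_L},
#'   \code{v_ml_um_s}, \code{error}.
#' @export
sweep_thickness <- function(base, thickness_um = 2:10,
                            spacing_L = c(0.55, 0.73, 0.91)) {
  grid <- expand.grid(ml_thickness_um = thickness_um, spacing_L = spacing_L)
  res <- lapply(seq_len(nrow(grid)), function(i)
    .sweep_cell(base, ml_thickness_um = grid$ml_thickness_um[i],
                spacing_L = grid$spacing_L[i]))
  cbind(grid, do.call(rbind, res))
}

#' Cilia-density sweep
#'
#' Runs the spacing sequence at each ML thickness and fits the mean ML
#' velocity linearly against cilia density (1/spacing), reporting R^2.
#'
#' @param base an [mcc_config()].
#' @param spacing_L spacing sequence (units of L).
#' @param thickness_um ML thickness values (um).
#' @return List with \code{table} (data.frame) and \code{fits}
#'   (per-thickness linear fit of v against density, with \code{r_squared}).
#' @export
sweep_density <- function(base, spacing_L = c(1.09, 0.91, 0.78, 0.69, 0.6, 0.55),
                          thickness_um = 4) {
  grid <- expand.grid(spacing_L = spacing_L, ml_thickness_um = thickness_um)
  res <- lapply(seq_len(nrow(grid)), function(i)
    .sweep_cell(base, ml_thickness_um = grid$ml_thickness_um[i],
                spacing_L = grid$spacing_L[i]))
  tab <- cbind(grid, do.call(rbind, res))
  tab$density <- 1 / tab$spacing_L
  fits <- lapply(split(tab, tab$ml_thickness_um), function(d) {
    d <- d[!is.na(d$v_ml_um_s), ]
    if (nrow(d) < 2) return(NULL)
    fit <- lm(v_ml_um_s ~ density, data = d)
    list(slope = unname(coef(fit)[2]),
         r_squared = summary(fit)$r.squared)
  })
  list(table = tab, fits = fits)
}

#' Metachronal phase-difference sweep
#'
#' Runs the phase-difference sequence (channel length snapped so the phase
#' pattern closes periodically) at each spacing.
#'
#' @param base an [mcc_config()].
#' @param phase_diff_T phase differences (units of T).
#' @param spacing_L spacings (units of L).
#' @return data.frame with \code{phase_diff_T}, \code{spacing_L},
#'   \code{v_ml_um_s}, \code{n_cilia}, \code{error}.
#' @export
sweep_phase <- function(base, phase_diff_T = c(0.03, 0.05, 0.075, 0.1,
                                               0.133, 0.167, 0.2, 0.25),
                        spacing_L = 0.55) {
  grid <- expand.grid(phase_diff_T = phase_diff_T, spacing_L = spacing_L)
  res <- lapply(seq_len(nrow(grid)), function(i)
    .sweep_cell(base, spacing_L = grid$spacing_L[i],
                phase_diff_T = grid$phase_diff_T[i],
                enforce_closure = TRUE))
  cbind(grid, do.call(rbind, res))
}

#' Particle-migration study
#'
#' Seeds 20 hard particles at each (diameter, initial height) combination,
#' runs the reference flow, and classifies each case: "reached-top" if the
#' mean particle height attains the cilia-tip region (y >= cilium length),
#' else "confined".
#'
#' @param base an [mcc_config()].
#' @param diameter_um particle diameters (um).
#' @param y0_um initial heights (um).
#' @param n_particles particles per case.
#' @param duration_T run length per case (beat periods).
#' @param tip_um cilia-tip height defining the "top area" (um).
#' @return List with \code{table} (classification + crossing time per case)
#'   and \code{trajectories} (named list of mean-height data.frames).
#' @export
particle_study <- function(base, diameter_um = 0.4,
                           y0_um = c(2, 2.5, 3, 3.5, 4, 4.5, 5, 5.5),
                           n_particles = 20, duration_T = 50,
                           tip_um = 5.5) {
  grid <- expand.grid(diameter_um = diameter_um, y0_um = y0_um)
  rows <- list(); trajs <- list()
  for (i in seq_len(nrow(grid))) {
    d <- grid$diameter_um[i]; y0 <- grid$y0_um[i]
    key <- paste0("d", d, "_y", y0)
    r <- tryCatch({
      cfg <- .clone_config(base, duration_T = duration_T,
                           particles = list(n = n_particles,
                                            diameter_um = d, y0_um = y0))
      run <- run_mcc(cfg)
      mh <- mean_particle_height(run$particle_t_T, run$particle_y_um)
      cross <- tip_crossing_time(mh$t_T, mh$y_um, tip_um)
      trajs[[key]] <- mh
      data.frame(crossing_T = cross,
                 classified = if (is.finite(cross)) "reached-top" else "confined",
                 error = NA_character_)
    }, error = function(e)
      data.frame(crossing_T = NA_real_, classified = NA_character_,
                 error = conditionMessage(e)))
    rows[[i]] <- r
  }
  list(table = cbind(grid, do.call(rbind, rows)), trajectories = trajs)
}

# Re-build a config with some fields replaced, run it, and return the
# one-row summary (errors recorded, not raised).
.sweep_cell <- function(base, ...) {
  tryCatch({
    cfg <- .clone_config(base, ...)
    run <- run_mcc(cfg)
    data.frame(v_ml_um_s = run$v_ml_um_s, n_cilia = cfg$n_cilia,
               max_strain_pct = run$max_strain_pct, error = NA_character_)
  }, error = function(e)
    data.frame(v_ml_um_s = NA_real_, n_cilia = NA_integer_,
               max_strain_pct = NA_real_, error = conditionMessage(e)))
}

.clone_config <- function(base, ...) {
  keep <- c("resolution", "duration_T", "ml_thickness_um", "pcl_depth_um",
            "spacing_L", "phase_diff_T", "enforce_closure", "channel_um",
            "beat_amplitude", "beat_asymmetry", "beat_wave_width",
            "beat_recline", "We", "visc_ratio", "Rv",
            "nu_pcl", "steps_per_T", "freq_hz", "ks", "kb", "ksl",
            "mem_ks", "mem_kb",
            "n_tracers", "particles", "seed", "sample_per_T")
  args <- base[keep]
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(mcc_config, args)
}
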