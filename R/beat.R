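#' Generate the default two-stroke ciliary beat
#'
#' Builds the prescribed virtual-cilium posture table for one beat cycle.
#' The beat is planar and two-stroke: during the effective stroke (cycle
#' fraction \code{asymmetry}) the cilium stays straight and pivots about its
#' root, sweeping the tip forward through \code{2 * amplitude} radians;
#' during the recovery stroke a curvature wave travels from root to tip,
#' returning the cilium at low tip height. Postures are parameterized by the
#' tangent angle and integrated along arclength, so every posture has exactly
#' arc length \code{L} (near-inextensible beat) and a fixed root. The tip
#' path encloses a nonzero area, the requirement for net pumping at low
#' Reynolds number.
#'
#' @param n_nodes nodes per cilium (>= 5).
#' @param L cilium length in lattice units.
#' @param amplitude half-sweep angle of the effective stroke (radians). The
#'   package default is calibrated so the reference configuration (cilium
#'   spacing 0.55 L) transports mucus at about 42 um/s; see [mcc_config()].
#' @param asymmetry fraction of the cycle spent in the effective stroke.
#' @param wave_width recovery-stroke curvature-wave width (fraction of L).
#' @param recline fraction by which the distal section reclines toward the
#'   wall during recovery (0 = return at stroke height, 1 = flat on the
#'   wall); controls the height asymmetry of the two strokes.
#' @param n_phase number of tabulated phases.
#' @param frequency beat frequency in Hz (20 Hz default).
#' @param direction +1 sweeps the effective stroke toward +x, -1 mirrors it.
#' @return A \code{beat_waveform}: list with \code{table}
#'   (\code{n_phase x n_nodes x 2} positions relative to the root),
#'   \code{n_nodes}, \code{n_phase}, \code{L}, \code{frequency},
#'   \code{amplitude}, \code{asymmetry}, \code{direction}.
#' @export
default_beat_generator <- function(n_nodes = 56, L = 55, amplitude = 0.9,
                                   asymmetry = 0.35, wave_width = 0.35,
                                   recline = 0.7, n_phase = 120,
                                   frequency = 20, direction = 1) {
  stopifnot(n_nodes >= 5, L > 0, amplitude >= 0, n_phase >= 2,
            asymmetry > 0, asymmetry < 1)
  if (amplitude > pi / 2)
    stop("default_beat_generator: amplitude beyond pi/2 sweeps below the wall")
  ds <- L / (n_nodes - 1)
  smoothstep <- function(r) {
    r <- pmin(pmax(r, 0), 1)
    r * r * (3 - 2 * r)
  }
  tab <- array(0, c(n_phase, n_nodes, 2))
  smid <- (seq_len(n_nodes - 1) - 0.5) / (n_nodes - 1) # segment midpoints s/L
  for (ip in seq_len(n_phase)) {
    phi <- (ip - 1) / n_phase
    if (phi < asymmetry) {           # effective stroke: straight, pivoting
      u <- phi / asymmetry
      psi <- rep(pi / 2 + amplitude * cos(pi * u), n_nodes - 1)
    } else {                         # recovery: root-to-tip curvature wave
      v <- (phi - asymmetry) / (1 - asymmetry)
      # ahead of the wave the distal section reclines toward the wall,
      # keeping the return path low (the height asymmetry that makes the
      # two-stroke cycle pump at low Reynolds number)
      th_min <- pi / 2 - amplitude
      # the recline vanishes with the amplitude (a zero-amplitude beat must
      # collapse to the vertical resting cilium)
      th_ahead <- th_min * (1 - recline * min(1, amplitude / 0.5) * sin(pi * v))
      arg <- (v * (1 + wave_width) - smid) / wave_width
      psi <- th_ahead + (pi / 2 + amplitude - th_ahead) * smoothstep(arg)
    }
    if (direction < 0) psi <- pi - psi
    tab[ip, , 1] <- c(0, cumsum(ds * cos(psi)))
    tab[ip, , 2] <- c(0, cumsum(ds * sin(psi)))
  }
  wf <- structure(list(table = tab, n_nodes = n_nodes, n_phase = n_phase,
                       L = L, ds = ds, frequency = frequency,
                       amplitude = amplitude, asymmetry = asymmetry,
                       direction = direction),
                  class = "beat_waveform")
  validate_beat_waveform(wf)
  wf
}

#' Validate a beat waveform
#'
#' Checks the posture-table invariants: at least two phases (a cycle),
#' a fixed root node, and per-posture arc length within 1\% of \code{L}.
#'
#' @param wf a \code{beat_waveform}.
#' @return \code{wf}, invisibly; stops with the failed check named otherwise.
#' @export
validate_beat_waveform <- function(wf) {
  if (wf$n_phase < 2)
    stop("beat_waveform: single-phase table, cycle undefined")
  root <- wf$table[, 1, , drop = FALSE]
  if (max(abs(sweep(root, 3, root[1, 1, ]))) > 1e-9)
    stop("beat_waveform: root node moves across phases")
  arc <- apply(wf$table, 1, function(p) {
    P <- matrix(p, ncol = 2)
    sum(sqrt(diff(P[, 1])^2 + diff(P[, 2])^2))
  })
  if (any(abs(arc - wf$L) / wf$L > 0.01))
    stop("beat_waveform: posture arc length deviates more than 1% from L")
  invisible(wf)
}

#' Evaluate virtual-cilium postures at a phase
#'
#' Linear-periodic interpolation of the posture table in phase.
#'
#' @param wf a \code{beat_waveform}.
#' @param phase beat phase (any real; used modulo 1).
#' @return \code{n_nodes x 2} matrix of positions relative to the root.
#' @export
beat_posture <- function(wf, phase) {
  p <- phase %% 1
  x <- p * wf$n_phase
  i0 <- floor(x) %% wf$n_phase
  w <- x - floor(x)
  i1 <- (i0 + 1) %% wf$n_phase
  (1 - w) * wf$table[i0 + 1, , ] + w * wf$table[i1 + 1, , ]
}

#' Write a beat table to CSV
#'
#' Plain-text format: columns \code{phase_index, node_index, x, y}.
#'
#' @param wf a \code{beat_waveform}.
#' @param file path.
#' @export
write_beat_table <- function(wf, file) {
  idx <- expand.grid(node_index = seq_len(wf$n_nodes),
                     phase_index = seq_len(wf$n_phase))
  df <- data.frame(phase_index = idx$phase_index, node_index = idx$node_index,
                   x = as.vector(t(wf$table[, , 1])),
                   y = as.vector(t(wf$table[, , 2])))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Load a beat table from CSV
#'
#' Reads a posture table written by [write_beat_table()] (or produced
#' externally in the same layout), optionally resampling in phase with
#' periodic cubic interpolation, and validates the waveform invariants.
#'
#' @param file CSV with columns \code{phase_index, node_index, x, y}.
#' @param L nominal cilium length; defaults to the arc length of the first
#'   posture.
#' @param frequency beat frequency (Hz).
#' @param n_phase optional phase count to resample to (periodic cubic
#'   spline); \code{NULL} keeps the file's phases.
#' @return A \code{beat_waveform}.
#' @export
load_beat_table <- function(file, L = NULL, frequency = 20, n_phase = NULL) {
  df <- read.csv(file)
  need <- c("phase_index", "node_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("load_beat_table: file must have columns ", paste(need, collapse = ", "))
  np <- max(df$phase_index)
  nn <- max(df$node_index)
  if (np < 2) stop("beat_waveform: single-phase table, cycle undefined")
  tab <- array(NA_real_, c(np, nn, 2))
  tab[cbind(df$phase_index, df$node_index, 1)] <- df$x
  tab[cbind(df$phase_index, df$node_index, 2)] <- df$y
  if (anyNA(tab)) stop("load_beat_table: incomplete phase x node table")
  if (!is.null(n_phase) && n_phase != np) {
    ph0 <- (seq_len(np) - 1) / np
    ph1 <- (seq_len(n_phase) - 1) / n_phase
    res <- array(0, c(n_phase, nn, 2))
    for (k in seq_len(nn)) for (cc in 1:2) {
      sp <- spline(c(ph0, 1), c(tab[, k, cc], tab[1, k, cc]),
                   method = "periodic", xout = ph1)
      res[, k, cc] <- sp$y
    }
    tab <- res
    np <- n_phase
  }
  if (is.null(L)) {
    P <- matrix(tab[1, , ], ncol = 2)
    L <- sum(sqrt(diff(P[, 1])^2 + diff(P[, 2])^2))
  }
  wf <- structure(list(table = tab, n_nodes = nn, n_phase = np, L = L,
                       ds = L / (nn - 1), frequency = frequency,
                       amplitude = NA_real_, asymmetry = NA_real_,
                       direction = NA_real_),
                  class = "beat_waveform")
  validate_beat_waveform(wf)
  wf
}

#' Snap the channel length to the metachronal closure constraint
#'
#' Under periodic boundaries the first and last cilium must keep the proper
#' phase relation, which requires \code{n_cilia * phase_diff} to be an
#' integer number of cycles. Chooses the cilium count minimizing the
#' deviation from the default channel length subject to that constraint.
#'
#' @param spacing inter-cilium distance (lattice units).
#' @param phase_diff adjacent-cilium phase offset (fraction of the beat
#'   period T).
#' @param nx_default target channel length (lattice units).
#' @param max_factor give up if no feasible count exists below
#'   \code{max_factor} times the unconstrained count.
#' @return List \code{(n_cilia, channel_length)} with
#'   \code{channel_length = round(n_cilia * spacing)}.
#' @export
adjust_channel_length <- function(spacing, phase_diff, nx_default = 600,
                                  max_factor = 8) {
  stopifnot(spacing > 0, phase_diff >= 0)
  n0 <- max(1, round(nx_default / spacing))
  if (phase_diff == 0) {
    n <- n0
  } else {
    # rational approximation p/q of the phase offset (q <= 200)
    q <- NA
    for (qq in 1:200) {
      if (abs(phase_diff * qq - round(phase_diff * qq)) < 0.008) {
        q <- qq; break
      }
    }
    if (is.na(q))
      stop("adjust_channel_length: phase_diff has no small rational form")
    p <- round(phase_diff * q)
    g <- .gcd(p, q)
    mult <- q / g            # n must be a multiple of this
    cand <- mult * seq_len(ceiling(max_factor * n0 / mult))
    if (!length(cand))
      stop("adjust_channel_length: no feasible cilium count")
    n <- cand[which.min(abs(cand * spacing - nx_default))]
    if (n > max_factor * n0)
      stop("adjust_channel_length: no feasible cilium count within ",
           max_factor, "x the default channel")
  }
  list(n_cilia = as.integer(n), channel_length = as.integer(round(n * spacing)))
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Lay out the cilia array
#'
#' Places \code{n_cilia} root positions at even spacing along the channel and
#' assigns the metachronal phase offsets \code{phi_k = k * phase_diff}; the
#' instantaneous phase of cilium k is \code{(t/T + phi_k) mod 1}, so the
#' constant-phase crest travels at speed \code{spacing / phase_diff} per beat
#' period.
#'
#' @param spacing_L inter-cilium distance in units of the cilium length L.
#' @param phase_diff_T adjacent-cilium phase offset in units of T.
#' @param L cilium length (lattice units).
#' @param nx_target desired channel length (lattice units).
#' @param enforce_closure snap the channel so the phase pattern closes
#'   periodically (required for phase sweeps).
#' @return A \code{cilia_array}: list with \code{n_cilia}, \code{spacing},
#'   \code{channel_length}, \code{roots} (x positions), \code{phase_off}.
#' @export
build_cilia_array <- function(spacing_L, phase_diff_T, L, nx_target = 600,
                              enforce_closure = FALSE) {
  spacing <- spacing_L * L
  if (spacing < 2) stop("build_cilia_array: spacing below 2 lattice units")
  if (enforce_closure) {
    adj <- adjust_channel_length(spacing, phase_diff_T, nx_target)
    n <- adj$n_cilia
    nx <- adj$channel_length
  } else {
    n <- max(1, round(nx_target / spacing))
    nx <- as.integer(round(n * spacing))
  }
  sp_actual <- nx / n
  structure(list(n_cilia = n, spacing = sp_actual, spacing_L = sp_actual / L,
                 channel_length = nx,
                 roots = sp_actual * (seq_len(n) - 1),
                 phase_off = phase_diff_T * (seq_len(n) - 1),
                 phase_diff_T = phase_diff_T),
            class = "cilia_array")
}
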