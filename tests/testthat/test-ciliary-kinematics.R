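test_that("generated beat waveforms satisfy the posture-table invariants", {
  wf <- default_beat_generator(n_nodes = 28, L = 27.5, amplitude = 0.6)
  # fixed root across phases
  expect_equal(max(abs(wf$table[, 1, ])), 0)
  # every posture has arc length L within 1%
  arcs <- apply(wf$table, 1, function(p) {
    P <- matrix(p, ncol = 2)
    sum(sqrt(diff(P[, 1])^2 + diff(P[, 2])^2))
  })
  expect_true(all(abs(arcs - wf$L) / wf$L <= 0.01))
  # periodic in phase
  expect_equal(beat_posture(wf, 0), beat_posture(wf, 1), tolerance = 1e-13)
})

test_that("zero amplitude collapses to the vertical resting cilium", {
  wf <- default_beat_generator(n_nodes = 20, L = 19, amplitude = 0)
  for (ph in c(0, 0.3, 0.77)) {
    P <- beat_posture(wf, ph)
    expect_equal(P[, 1], rep(0, 20), tolerance = 1e-12)
    expect_equal(P[, 2], seq(0, 19, length.out = 20), tolerance = 1e-12)
  }
})

test_that("the tip path encloses a nonzero area (pumping asymmetry)", {
  wf <- default_beat_generator(n_nodes = 28, L = 27.5, amplitude = 0.6)
  tip <- wf$table[, wf$n_nodes, ]
  n <- nrow(tip)
  shoelace <- 0.5 * abs(sum(tip[, 1] * tip[c(2:n, 1), 2]
                            - tip[c(2:n, 1), 1] * tip[, 2]))
  expect_gt(shoelace, 1)   # lattice units^2; degenerate paths give ~0
  # mirrored beat encloses the same area
  wfm <- default_beat_generator(n_nodes = 28, L = 27.5, amplitude = 0.6,
                                direction = -1)
  tipm <- wfm$table[, wfm$n_nodes, ]
  shoelace_m <- 0.5 * abs(sum(tipm[, 1] * tipm[c(2:n, 1), 2]
                              - tipm[c(2:n, 1), 1] * tipm[, 2]))
  expect_equal(shoelace_m, shoelace, tolerance = 1e-10)
})

test_that("beat tables round-trip through CSV bit-identically", {
  wf <- default_beat_generator(n_nodes = 15, L = 14, amplitude = 0.5,
                               n_phase = 24)
  path <- tempfile(fileext = ".csv")
  write_beat_table(wf, path)
  wf2 <- load_beat_table(path, L = wf$L)
  expect_identical(dim(wf2$table), dim(wf$table))
  expect_equal(wf2$table, wf$table, tolerance = 1e-12)
  unlink(path)
})

test_that("invalid beat tables are rejected with the failed check named", {
  wf <- default_beat_generator(n_nodes = 15, L = 14, amplitude = 0.5,
                               n_phase = 24)
  # moving root
  bad <- wf; bad$table[3, 1, 1] <- 0.5
  expect_error(validate_beat_waveform(bad), "root")
  # single phase
  path <- tempfile(fileext = ".csv")
  df <- data.frame(phase_index = 1, node_index = 1:15,
                   x = wf$table[1, , 1], y = wf$table[1, , 2])
  write.csv(df, path, row.names = FALSE)
  expect_error(load_beat_table(path), "single-phase")
  unlink(path)
})

test_that("channel length snaps to the metachronal closure constraint", {
  # phase 0.25: cilium count must be a multiple of 4, nearest the default
  adj <- adjust_channel_length(30.25, 0.25, nx_default = 600)
  expect_equal(adj$n_cilia %% 4, 0)
  expect_equal(adj$n_cilia, 20)
  # phase 0.1: multiples of 10
  adj <- adjust_channel_length(30.25, 0.1, nx_default = 600)
  expect_equal(adj$n_cilia %% 10, 0)
  # phase 0.133 ~ 2/15: multiples of 15; verify against brute force
  adj <- adjust_channel_length(30.25, 2 / 15, nx_default = 600)
  feasible <- Filter(function(n) abs(n * 2 / 15 - round(n * 2 / 15)) < 1e-9,
                     1:200)
  best <- feasible[which.min(abs(feasible * 30.25 - 600))]
  expect_equal(adj$n_cilia, best)
  expect_equal(adj$channel_length, round(best * 30.25))
})

test_that("cilia arrays tile the channel with metachronal phase offsets", {
  arr <- build_cilia_array(0.55, 0.02, L = 55, nx_target = 600,
                           enforce_closure = TRUE)
  expect_equal((arr$n_cilia * 0.02) %% 1, 0)
  expect_equal(length(arr$roots), arr$n_cilia)
  expect_equal(diff(arr$roots), rep(arr$spacing, arr$n_cilia - 1),
               tolerance = 1e-12)
  expect_equal(arr$phase_off, 0.02 * (seq_len(arr$n_cilia) - 1))
  # synchronous limit: all offsets zero
  arr0 <- build_cilia_array(0.55, 0, L = 55, nx_target = 600)
  expect_true(all(arr0$phase_off == 0))
  # metachronal wave speed by construction: spacing / phase_diff per T
  expect_equal(arr$spacing / 0.02,
               (arr$roots[2] - arr$roots[1]) / (arr$phase_off[2] - arr$phase_off[1]))
  expect_error(build_cilia_array(0.01, 0, L = 55), "spacing")
})
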