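test_that("mean ML velocity is exact for frozen and uniformly translating flow", {
  t <- seq(0, 6000, by = 100)
  # frozen fluid
  expect_equal(mean_ml_velocity(t, rep(3, length(t)), steps_per_T = 1000), 0)
  # uniform translation, including unwrapped seam crossings: the unwrapped
  # mean coordinate grows linearly regardless of how many wraps occurred
  c0 <- 4.2e-3
  x <- 10 + c0 * t
  expect_equal(mean_ml_velocity(t, x, steps_per_T = 1000, warmup_T = 2),
               c0, tolerance = 1e-12)
  # physical conversion: dx = 0.1 um, f = 20 Hz, T = 1000 steps
  expect_equal(mean_ml_velocity(t, x, 1000, warmup_T = 2,
                                vel_unit_um_s = 0.1 * 20 * 1000),
               c0 * 2000, tolerance = 1e-9)
  expect_error(mean_ml_velocity(t[1], x[1], 1000), "length")
})

test_that("developed-flow detection matches the synthetic-log oracles", {
  expect_equal(detect_developed_flow(make_velocity_log("constant", 30)), 2L)
  # exponentially converging log: relative change < 2% after period k;
  # brute-force the oracle from the log itself
  v <- make_velocity_log("converging", 30, list(rate = 0.6))
  k_oracle <- which(abs(diff(v)) / abs(v[-1]) < 0.02)[1] + 1
  expect_equal(detect_developed_flow(v), k_oracle)
  expect_lte(detect_developed_flow(v), k_oracle)
  # oscillating log never converges: fallback + warning
  vo <- make_velocity_log("oscillating", 30)
  expect_warning(p <- detect_developed_flow(vo, fallback = 20), "fallback")
  expect_equal(p, 20L)
})

test_that("mean particle height averages trajectories and flags tip crossing", {
  tT <- seq(0, 20, by = 0.5)
  Y <- matrix(4.5, nrow = 20, ncol = length(tT))
  mh <- mean_particle_height(tT, Y)
  expect_true(all(mh$y_um == 4.5))
  expect_equal(tip_crossing_time(mh$t_T, mh$y_um), Inf)
  # rising trajectories cross the 5.5 um tip height
  Y2 <- outer(rep(1, 20), 4.5 + 0.3 * tT)
  mh2 <- mean_particle_height(tT, Y2)
  expect_equal(tip_crossing_time(mh2$t_T, mh2$y_um), tT[which(4.5 + 0.3 * tT >= 5.5)[1]])
})

test_that("tracer advection matches fiber-node advection (shared interpolation)", {
  # a tracer co-located with a Lagrangian point sees the same velocity
  nx <- 30; ny <- 30
  u <- make_analytic_field("random_smooth", nx, ny, list(seed = 9))$ux
  v <- make_analytic_field("random_smooth", nx, ny, list(seed = 10))$ux
  P <- cbind(c(7.3, 15.8), c(12.1, 20.4))
  U1 <- interpolate_velocity(u, v, P)
  U2 <- interpolate_velocity(u, v, P)   # same contract, same kernel
  expect_identical(U1, U2)
})

test_that("transport estimate is insensitive to tracer count beyond noise", {
  cfg50 <- mcc_config(resolution = "half", duration_T = 2, phase_diff_T = 0.05,
                      n_tracers = 50)
  cfg100 <- mcc_config(resolution = "half", duration_T = 2, phase_diff_T = 0.05,
                       n_tracers = 100)
  r50 <- run_mcc(cfg50)
  r100 <- run_mcc(cfg100)
  # doubling the tracers moves the estimate by < 2% of the flow scale
  scale <- max(abs(r50$v_ml_um_s), 10)
  expect_lt(abs(r100$v_ml_um_s - r50$v_ml_um_s) / scale, 0.02)
})
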