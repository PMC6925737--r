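test_that("analytic fields carry their closed-form derivatives", {
  f <- make_analytic_field("uniform", 10, 10, list(c = c(0.1, 0)))
  expect_true(all(f$ux == 0.1))
  expect_true(all(f$dux_dy == 0))
  f <- make_analytic_field("shear", 10, 10, list(gammadot = 0.01))
  expect_true(all(f$Dxy == 0.005))
  f <- make_analytic_field("poiseuille", 10, 41, list(umax = 0.1, Ly = 40))
  expect_equal(f$ux[1, 21], 0.1)  # centerline
  expect_equal(f$ux[1, 1], 0)
})

test_that("random smooth fields are reproducible from their seed", {
  a <- make_analytic_field("random_smooth", 12, 12, list(seed = 42))
  b <- make_analytic_field("random_smooth", 12, 12, list(seed = 42))
  expect_identical(a$ux, b$ux)
  d <- make_analytic_field("random_smooth", 12, 12, list(seed = 43))
  expect_false(identical(a$ux, d$ux))
})

test_that("fiber shapes expose usable force oracles", {
  sh <- make_fiber_shape("straight", n = 11, params = list(strain = 0.01))
  seg <- sqrt(diff(sh$X[, 1])^2 + diff(sh$X[, 2])^2)
  expect_equal(seg, rep(1.01, 10), tolerance = 1e-12)
  sh <- make_fiber_shape("sinusoid", n = 41, params = list(A = 0.3, k = 0.4))
  expect_equal(sh$X[, 2], 0.3 * sin(0.4 * (0:40)))
  o <- sh$bend_oracle_y(2)
  expect_equal(o, -2 * 0.3 * 0.4^4 * sin(0.4 * (0:40)))
})

test_that("synthetic velocity logs have the advertised convergence shapes", {
  expect_equal(make_velocity_log("constant", 5), rep(1, 5))
  v <- make_velocity_log("converging", 20, list(rate = 0.5))
  expect_true(all(diff(v) > 0))
  expect_lt(abs(v[20] - 1), 1e-5)
  vo <- make_velocity_log("oscillating", 6)
  expect_equal(vo[1:2], c(0.5, 1.5))
})
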