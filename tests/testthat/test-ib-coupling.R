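test_that("delta kernels satisfy the discrete partition of unity", {
  for (kind in c("peskin4", "hat2")) {
    k <- ib_kernel(kind)
    for (r in c(0, 0.1, 0.374, 0.5, 0.99)) {
      expect_equal(sum(k$phi(r - (-4:5))), 1, tolerance = 1e-12)
    }
    expect_true(all(k$phi(seq(-3, 3, by = 0.17)) >= 0))
    expect_equal(k$phi(k$support), 0)
    expect_equal(k$phi(-k$support - 0.5), 0)
  }
})

test_that("spread conserves total force at on- and off-grid positions", {
  nx <- 16; ny <- 16
  for (X in list(cbind(8, 8), cbind(7.37, 9.81), cbind(0.2, 8.5))) {
    sp <- spread_force(X, cbind(1, 0), nx, ny)
    expect_equal(sum(sp$fx), 1, tolerance = 1e-12)
    expect_equal(sum(sp$fy), 0, tolerance = 1e-12)
  }
  expect_error(spread_force(cbind(5, -3), cbind(1, 0), nx, ny), "outside")
})

test_that("equal and opposite point forces carry zero net force and the pair torque", {
  nx <- 32; ny <- 32
  X <- rbind(c(12.3, 14.7), c(18.9, 17.2))
  F <- rbind(c(0.4, -0.2), c(-0.4, 0.2))
  sp <- spread_force(X, F, nx, ny)
  expect_lt(abs(sum(sp$fx)), 1e-12)
  expect_lt(abs(sum(sp$fy)), 1e-12)
  # torque about the origin: sum x cross f over the lattice vs the pair value
  xg <- matrix(rep(0:(nx - 1), ny), nx, ny)
  yg <- matrix(rep(0:(ny - 1), each = nx), nx, ny)
  tq_lattice <- sum(xg * sp$fy - yg * sp$fx)
  tq_pair <- sum(X[, 1] * F[, 2] - X[, 2] * F[, 1])
  expect_equal(tq_lattice, tq_pair, tolerance = 1e-10)
})

test_that("interpolation is consistent for uniform and linear fields", {
  nx <- 24; ny <- 20
  U <- interpolate_velocity(matrix(0.3, nx, ny), matrix(-0.12, nx, ny),
                            cbind(11.83, 7.21))
  expect_equal(U[1, ], c(0.3, -0.12), tolerance = 1e-13)
  # linear field u_x = a y reproduced at off-grid points (the 4-point kernel
  # interpolates linear functions exactly away from boundaries)
  a <- 0.01
  ux <- matrix(rep(a * (0:(ny - 1)), each = nx), nx, ny)
  for (Y in c(5.5, 9.13, 12.77)) {
    U <- interpolate_velocity(ux, 0 * ux, cbind(6.4, Y))
    expect_equal(U[1, 1], a * Y, tolerance = 1e-12)
  }
  # 2-point kernel at a node returns the exact nodal value
  U <- interpolate_velocity(ux, 0 * ux, cbind(6, 9), ib_kernel("hat2"))
  expect_equal(U[1, 1], a * 9, tolerance = 1e-14)
})

test_that("spread and interpolation are discrete adjoints (power balance)", {
  set.seed(11)
  nx <- 28; ny <- 24
  X <- cbind(runif(9, 0, nx), runif(9, 4, ny - 5))
  F <- matrix(rnorm(18), 9, 2)
  u <- make_analytic_field("random_smooth", nx, ny, list(seed = 5))$ux
  v <- make_analytic_field("random_smooth", nx, ny, list(seed = 6))$ux
  for (kind in c("peskin4", "hat2")) {
    k <- ib_kernel(kind)
    sp <- spread_force(X, F, nx, ny, kernel = k)
    U <- interpolate_velocity(u, v, X, kernel = k)
    lhs <- sum(F[, 1] * U[, 1] + F[, 2] * U[, 2])
    rhs <- sum(sp$fx * u + sp$fy * v)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})
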