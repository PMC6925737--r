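test_that("straight resting fibers carry no elastic force", {
  for (ang in c(pi / 2, 0.3, 1.2)) {
    sh <- make_fiber_shape("straight", n = 21, params = list(angle = ang))
    fib <- fiber(sh$X, ks = 2, kb = 1)
    expect_equal(max(abs(stretching_force(fib))), 0, tolerance = 1e-12)
    expect_equal(max(abs(bending_force(fib))), 0, tolerance = 1e-12)
  }
})

test_that("uniform stretch gives end tensions ks * strain, zero interior", {
  eps <- 0.01
  sh <- make_fiber_shape("straight", n = 21,
                         params = list(angle = pi / 2, strain = eps))
  fib <- fiber(sh$X, ks = 2, kb = 1)
  Fs <- stretching_force(fib)
  n <- nrow(Fs)
  expect_equal(Fs[1, 2], 2 * eps, tolerance = 1e-10)
  expect_equal(Fs[n, 2], -2 * eps, tolerance = 1e-10)
  expect_lt(max(abs(Fs[2:(n - 1), ])), 1e-12)
})

test_that("internal forces sum to zero on randomly perturbed fibers", {
  set.seed(3)
  for (rep in 1:5) {
    X <- cbind(cumsum(runif(15, 0.7, 1.3)), cumsum(rnorm(15, 0, 0.3)))
    fib <- fiber(X, ks = 2, kb = 1)
    expect_lt(max(abs(colSums(stretching_force(fib)))), 1e-12)
    expect_lt(max(abs(colSums(bending_force(fib)))), 1e-10)
  }
  # closed chains too (membrane topology)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  Xc <- cbind(10 + 3 * cos(th) + (0:31), 10 + 2 * sin(th))
  fibc <- fiber(Xc, ks = 2, kb = 1, role = "membrane", closed = TRUE, Lx = 32)
  expect_lt(max(abs(colSums(stretching_force(fibc)))), 1e-10)
  expect_lt(max(abs(colSums(bending_force(fibc)))), 1e-10)
})

test_that("quadratic arcs feel no interior bending force", {
  sh <- make_fiber_shape("arc", n = 31, params = list(a = 0.005))
  fib <- fiber(sh$X, kb = 1)
  Fb <- bending_force(fib)
  # fourth difference of a quadratic vanishes away from the ends
  expect_lt(max(abs(Fb[4:28, 2])), 1e-12)
})

test_that("sinusoidal fibers reproduce the analytic fourth-derivative force", {
  sh <- make_fiber_shape("sinusoid", n = 121, ds = 1,
                         params = list(A = 0.4, k = 2 * pi / 30))
  fib <- fiber(sh$X, kb = 1.7)
  Fb <- bending_force(fib)
  oracle <- sh$bend_oracle_y(1.7)
  mid <- 35:85
  rel <- max(abs(Fb[mid, 2] - oracle[mid])) / max(abs(oracle))
  expect_lt(rel, 0.02)   # O(ds^2) stencil error at k ds ~ 0.2
})

test_that("virtual-spring driving force is the nodewise penalty", {
  sh <- make_fiber_shape("straight", n = 12)
  fib <- fiber(sh$X, role = "cilium")
  expect_equal(driving_force(fib, sh$X, ksl = 1), matrix(0, 12, 2))
  d <- c(0.3, -0.1)
  Y <- sweep(sh$X, 2, -d)
  Fc <- driving_force(fib, Y, ksl = 2)
  expect_equal(Fc, matrix(rep(2 * d, each = 12), 12, 2), tolerance = 1e-14)
  expect_error(driving_force(fib, Y[-1, ]), "mismatch")
  mem <- fiber(sh$X, role = "membrane")
  expect_error(driving_force(mem, Y), "cilia")
})

test_that("total fiber force gates the driving term by role", {
  sh <- make_fiber_shape("straight", n = 10)
  cil <- fiber(sh$X, role = "cilium")
  mem <- fiber(sh$X, role = "membrane")
  Y <- sh$X + 0.5
  expect_equal(total_fiber_force(mem), total_fiber_force(mem, Y))
  expect_false(isTRUE(all.equal(total_fiber_force(cil, Y),
                                total_fiber_force(mem))))
  # straight resting cilium with Y = X: nothing acts
  expect_equal(max(abs(total_fiber_force(cil, sh$X))), 0, tolerance = 1e-12)
})

test_that("a bent free fiber relaxes with monotone bending-energy decay", {
  # advected by its own spread force in a quiescent viscous fluid
  nx <- 48; ny <- 48
  s <- seq(0, 20, length.out = 21)
  X <- cbind(14 + s, 24 + 3 * sin(pi * s / 20))
  bend_energy <- function(X) {
    C <- diff(diff(X))
    sum(C^2) / 2
  }
  f <- fluid_field(nx, ny, tau = 2)
  E0 <- bend_energy(X)
  E <- E0
  n_up <- 0
  for (it in 1:150) {
    fib <- fiber(X, ks = 2, kb = 1)
    Fb <- stretching_force(fib) + bending_force(fib)
    sp <- spread_force(X, Fb, nx, ny)
    f$fx <- sp$fx; f$fy <- sp$fy
    f <- lbm_step(f, 1)
    U <- interpolate_velocity(f$ux, f$uy, X)
    X <- X + U
    Enew <- bend_energy(X)
    if (Enew > E + 1e-12) n_up <- n_up + 1
    E <- Enew
  }
  expect_equal(n_up, 0)
  expect_lt(E, 0.5 * E0)
})
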