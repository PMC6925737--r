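test_that("lattice spec satisfies the D2Q9 quadrature identities", {
  sp <- lattice_spec(10, 12)
  expect_equal(sum(sp$w), 1)
  expect_equal(colSums(sp$w * sp$e), c(0, 0))
  # second moment: sum w e_a e_b = cs^2 delta_ab
  M <- t(sp$e) %*% (sp$w * sp$e)
  expect_equal(M, diag(2) / 3, tolerance = 1e-14)
  expect_error(lattice_spec(2, 10), "nx")
})

test_that("equilibrium reproduces weights at rest and carries the moments", {
  g0 <- lbm_equilibrium(1, c(0, 0))
  expect_equal(g0, d2q9_w)
  # zeroth moment equals rho for arbitrary admissible input
  for (u in list(c(0.1, 0), c(0.03, -0.07), c(-0.1, 0.1))) {
    g <- lbm_equilibrium(1, u)
    expect_equal(sum(g), 1, tolerance = 1e-14)
  }
  # first moment at rho = 1, u = (0.1, 0): sum over the 9 terms evaluated
  # independently from the weight table
  g <- lbm_equilibrium(1, c(0.1, 0))
  eu <- d2q9_e[, 1] * 0.1
  g_hand <- d2q9_w * (1 + 3 * eu + 4.5 * eu^2 - 1.5 * 0.01)
  expect_equal(g, g_hand, tolerance = 1e-14)
  expect_equal(colSums(g * d2q9_e), c(0.1, 0), tolerance = 1e-14)
  expect_error(lbm_equilibrium(-1, c(0, 0)), "positive")
  expect_error(lbm_equilibrium(NaN, c(0, 0)), "finite")
})

test_that("Guo source term has the moment structure of the forcing scheme", {
  expect_equal(lbm_guo_source(c(0, 0), c(0, 0), tau = 1), rep(0, 9))
  # zero velocity: zeroth moment vanishes since sum w e = 0
  G <- lbm_guo_source(c(0, 0), c(1e-5, 0), tau = 1)
  expect_lt(abs(sum(G)), 1e-16)
  # first moment equals (1 - 1/(2 tau)) f, by explicit summation over the 9
  # directions for several tau and force directions
  for (tau in c(0.6, 1, 2.5)) {
    for (f in list(c(1e-5, 0), c(2e-5, -1e-5))) {
      G <- lbm_guo_source(c(0, 0), f, tau = tau)
      expect_lt(max(abs(colSums(G * d2q9_e) - (1 - 0.5 / tau) * f)), 1e-15)
    }
  }
  expect_error(lbm_guo_source(c(0, 0), c(0, 0), tau = 0.4), "tau")
})

test_that("macroscopic moments include the half-force correction", {
  m <- lbm_macroscopic(d2q9_w)
  expect_equal(m$rho, matrix(1, 1, 1))
  expect_equal(m$ux[1, 1], 0)
  expect_equal(m$p[1, 1], 1 / 3)
  g <- lbm_equilibrium(1, c(0.05, 0.02))
  m <- lbm_macroscopic(g)
  expect_equal(m$ux[1, 1], 0.05, tolerance = 1e-14)
  expect_equal(m$uy[1, 1], 0.02, tolerance = 1e-14)
  # resting distributions + body force: u = f dt / 2
  m <- lbm_macroscopic(lbm_equilibrium(1, c(0, 0)), f = c(1e-4, 0))
  expect_lt(abs(m$ux[1, 1] - 5e-5), 1e-16)
})

test_that("global equilibrium is a fixed point of collide-stream", {
  for (tau in c(0.55, 1, 3)) {
    f <- fluid_field(12, 9, tau = tau)
    f2 <- lbm_step(f, 7)
    expect_equal(f2$g, f$g, tolerance = 1e-14)
  }
})

test_that("a single-node perturbation spreads per the velocity set at tau=1", {
  nx <- 9; ny <- 9
  f <- fluid_field(nx, ny, tau = 1)
  eps <- 1e-6
  # bump every population at the center node by eps * w_i (a pure density
  # perturbation that stays at equilibrium shape)
  for (q in 1:9) f$g[5, 5, q] <- f$g[5, 5, q] + eps * d2q9_w[q]
  f2 <- lbm_step(f, 1)
  m <- lbm_macroscopic(f2$g)
  # at tau = 1 post-collision = equilibrium; each population moves one cell
  # along its velocity, so the excess density lands on the 9 neighbors in
  # proportion w_i
  for (q in 1:9) {
    i <- 5 + d2q9_e[q, 1]; j <- 5 + d2q9_e[q, 2]
    expect_lt(abs(m$rho[i, j] - 1 - eps * d2q9_w[q]), 1e-14)
  }
})

test_that("shear-wave decay recovers nu = cs^2 (tau - 1/2) within 1%", {
  for (tau in c(0.6, 1.0, 1.5)) {
    ny <- 128
    fld <- make_analytic_field("shear_wave", 4, ny, list(A = 0.01))
    f <- fluid_field(4, ny, tau = tau, u0 = list(fld$ux, fld$uy))
    n <- 300
    f <- lbm_step(f, n)
    nu_meas <- -log(max(f$ux) / 0.01) / (n * fld$k_wave^2)
    expect_equal(nu_meas, (tau - 0.5) / 3, tolerance = 0.01)
  }
})

test_that("mass is conserved to machine precision with closed boundaries", {
  set.seed(7)
  nx <- 20; ny <- 16
  u0 <- make_analytic_field("random_smooth", nx, ny, list(seed = 7))
  for (bc in list(list(bottom = "periodic", top = "periodic",
                       left = "periodic", right = "periodic"),
                  list(bottom = "noslip", top = "slip",
                       left = "periodic", right = "periodic"))) {
    f <- fluid_field(nx, ny, tau = 0.8, u0 = list(u0$ux, u0$uy), bc = bc)
    m0 <- sum(lbm_macroscopic(f$g)$rho)
    f <- lbm_step(f, 1000)
    m1 <- sum(lbm_macroscopic(f$g)$rho)
    expect_lt(abs(m1 - m0) / m0, 1e-12)
  }
})

test_that("body-force-driven channel matches Poiseuille closed forms", {
  # both walls no-slip (bounce-back): parabola between the halfway walls
  nx <- 6; ny <- 40; tau <- 0.9; nu <- (tau - 0.5) / 3
  G <- 1e-6
  f <- fluid_field(nx, ny, tau = tau,
                   bc = list(bottom = "noslip", top = "noslip",
                             left = "periodic", right = "periodic"))
  f$fx <- matrix(G, nx, ny)
  f <- lbm_step(f, 30000)
  y <- (0:(ny - 1)) + 0.5           # walls at -1/2 and ny - 1/2
  H <- ny
  u_ref <- G / (2 * nu) * y * (H - y)
  err <- sqrt(sum((f$ux[3, ] - u_ref)^2) / sum(u_ref^2))
  expect_lt(err, 0.005)

  # bottom no-slip + top slip: half-Poiseuille, zero shear at the top
  f2 <- fluid_field(nx, ny, tau = tau,
                    bc = list(bottom = "noslip", top = "slip",
                              left = "periodic", right = "periodic"))
  f2$fx <- matrix(G, nx, ny)
  f2 <- lbm_step(f2, 30000)
  Hs <- ny                           # slip plane at ny - 1/2
  u_ref2 <- G / nu * y * (Hs - y / 2)
  err2 <- max(abs(f2$ux[3, ] - u_ref2)) / max(u_ref2)
  expect_lt(err2, 0.01)
})

test_that("inlet/outflow channel preserves the imposed parabolic profile", {
  nx <- 60; ny <- 21; Ly <- ny - 1; umax <- 0.04
  prof <- analytic_u(0:(ny - 1), umax, Ly)
  f <- fluid_field(nx, ny, tau = 0.9,
                   u0 = list(matrix(prof, nx, ny, byrow = TRUE),
                             matrix(0, nx, ny)),
                   bc = list(bottom = "noslip_nee", top = "noslip_nee",
                             left = "inlet", right = "outflow"),
                   inlet_ux = prof)
  f <- lbm_step(f, 8000)
  err <- max(abs(f$ux[30, ] - prof)) / umax
  expect_lt(err, 0.01)
})
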