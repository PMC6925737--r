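test_that("particle seeding places non-overlapping particles at height y0", {
  s <- seed_particles(20, diameter = 2, y0 = 22.5, nx = 300)
  expect_length(s$x, 20)
  expect_true(all(s$y == 22.5))
  expect_true(all(diff(sort(s$x)) > 2))      # no overlap
  expect_equal(s$radius, 1)
  s1 <- seed_particles(1, 2, 10, 300)
  expect_equal(s1$x, 150)
  expect_error(seed_particles(5, 2, 0.5, 300), "wall")
  expect_error(seed_particles(100, 4, 10, 300), "overlap")
})

test_that("repulsion is zero beyond the cutoff and pairwise antisymmetric", {
  expect_equal(repulsive_force(10, 10, 1,
                               others = list(x = 16, y = 10, radius = 1),
                               d_cut = 2),
               c(0, 0))
  # two particles at half-cutoff gap: equal magnitude, opposite, center line
  oA <- list(x = 14.5, y = 10, radius = 1)
  fA <- repulsive_force(10, 10, 1, others = oA, C = 2, d_cut = 5)
  fB <- repulsive_force(14.5, 10, 1,
                        others = list(x = 10, y = 10, radius = 1),
                        C = 2, d_cut = 5)
  expect_equal(fA, -fB, tolerance = 1e-14)
  expect_equal(fA[2], 0)
  expect_lt(fA[1], 0)
  # interpenetration caps the force magnitude at C with a warning
  expect_warning(
    fcap <- repulsive_force(10, 10, 1.2,
                            others = list(x = 11, y = 10, radius = 1.2),
                            C = 3, d_cut = 2),
    "interpenetration")
  expect_equal(sqrt(sum(fcap^2)), 3, tolerance = 1e-12)
  # wall gap
  fw <- repulsive_force(10, 1.5, 1, walls = c(0, 40), C = 1, d_cut = 2)
  expect_gt(fw[2], 0)
})

test_that("penalty coupling gives zero force at rest and drag against a stream", {
  nx <- 40; ny <- 40
  z <- matrix(0, nx, ny)
  h <- hydrodynamic_force_torque(20, 20, 0, 0, 0, radius = 2,
                                 ux = z, uy = z)
  expect_equal(h$force, c(0, 0))
  expect_equal(h$torque, 0)
  # uniform stream: drag antiparallel to relative velocity
  u <- matrix(0.05, nx, ny)
  h <- hydrodynamic_force_torque(20, 20, 0, 0, 0, radius = 2,
                                 ux = u, uy = z)
  expect_gt(h$force[1], 0)             # dragged along the stream
  expect_equal(h$force[2], 0, tolerance = 1e-12)
  h2 <- hydrodynamic_force_torque(20, 20, 0.05, 0, 0, radius = 2,
                                  ux = u, uy = z)
  expect_equal(h2$force, c(0, 0), tolerance = 1e-12)  # co-moving: no drag
})

test_that("penalty torque vanishes at half the shear vorticity (rotation rate)", {
  nx <- 40; ny <- 40
  g <- 0.01
  fld <- make_analytic_field("shear", nx, ny, list(gammadot = g))
  # torque zero when the particle spins at gammadot/2 with the vorticity sign
  om_free <- -g / 2
  h <- hydrodynamic_force_torque(20, 20.0, 0.2, 0, om_free, radius = 3,
                                 ux = fld$ux, uy = fld$uy, ns = 64)
  href <- hydrodynamic_force_torque(20, 20.0, 0.2, 0, 0, radius = 3,
                                    ux = fld$ux, uy = fld$uy, ns = 64)
  expect_lt(abs(h$torque), 0.1 * abs(href$torque))
})

test_that("explicit rigid-body update integrates the discrete dynamics", {
  p <- list(x = 0, y = 10, ux = 0, uy = 0, om = 0, ang = 0,
            mass = 2, inertia = 0.5)
  # zero force: uniform motion, constant spin
  p2 <- p; p2$ux <- 0.1; p2$om <- 0.05
  for (i in 1:10) p2 <- advance_particle(p2, c(0, 0), 0)
  expect_equal(p2$x, 1, tolerance = 1e-13)
  expect_equal(p2$ang, 0.5, tolerance = 1e-13)
  # constant force from rest: the explicit scheme's discrete quadratic
  # x(n) = F/m * n (n + 1) / 2 (velocity updated before position)
  p3 <- p
  n <- 25; F0 <- 0.02
  for (i in 1:n) p3 <- advance_particle(p3, c(F0, 0), 0)
  expect_equal(p3$x, F0 / p$mass * n * (n + 1) / 2, tolerance = 1e-12)
})

test_that("seeded particles stay rigid and inside the channel in a coupled run", {
  cfg <- mcc_config(resolution = "half", duration_T = 2, phase_diff_T = 0.05,
                    particles = list(n = 6, diameter_um = 0.4, y0_um = 4.5))
  run <- run_mcc(cfg, keep_state = TRUE)
  st <- run$state
  # no interpenetration with the walls over the run (centers inside, gap >= 0)
  expect_true(all(run$particle_y_um > 0.2 / 2))
  expect_true(all(run$particle_y_um < cfg$ny * cfg$dx_um))
  # surface points are regenerated from center + angle: rigidity is exact
  expect_true(all(is.finite(st$p_x)))
  # action-reaction: with no gravity the particle set only exchanges
  # momentum with the fluid; velocities stay bounded by the flow scale
  expect_lt(max(abs(st$p_ux), abs(st$p_uy)), 0.5)
})
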