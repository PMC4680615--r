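# Stokeslet, image system, ambient-flow derivatives, decay fits, tracers.

MU <- 1e-3
FLUID <- fluid_properties(viscosity = MU)

test_that("stokeslet has the Oseen longitudinal and transverse factors", {
  f <- 40
  src <- point_force(c(0, 0, 100), c(0, 0, f))
  r <- 25
  u_long <- stokeslet(src, c(0, 0, 100 + r), FLUID)
  expect_equal(u_long, c(0, 0, f / (4 * pi * MU * r)), tolerance = 1e-12)
  u_trans <- stokeslet(src, c(r, 0, 100), FLUID)
  expect_equal(u_trans, c(f * 0, 0, f / (8 * pi * MU * r)), tolerance = 1e-12)
  # linearity
  src2 <- point_force(c(0, 0, 100), c(0, 0, 2 * f))
  expect_equal(stokeslet(src2, c(3, -7, 120), FLUID),
               2 * stokeslet(src, c(3, -7, 120), FLUID), tolerance = 1e-12)
  expect_error(stokeslet(src, c(0, 0, 100), FLUID), "singular")
})

test_that("blake image system enforces no-slip on the wall", {
  set.seed(42)
  for (i in 1:20) {
    src <- point_force(c(runif(2, -50, 50), runif(1, 5, 80)), rnorm(3, 0, 30))
    wall_pt <- c(runif(2, -200, 200), 0)
    u_wall <- wall_velocity(src, wall_pt, FLUID, mode = "blake")
    # relative to the flow scale at the source height
    u_ref <- vnorm(stokeslet(src, src$position + c(0, 0, src$position[3]), FLUID))
    expect_lt(vnorm(u_wall) / u_ref, 1e-10)
  }
})

test_that("leading image reduces but does not cancel the wall slip", {
  src <- point_force(c(0, 0, 40), c(0, 0, -40))
  wall_pt <- c(30, 10, 0)
  u_free <- stokeslet(src, wall_pt, FLUID)
  u_lead <- wall_velocity(src, wall_pt, FLUID, mode = "leading")
  expect_gt(vnorm(u_lead), 0)
  expect_lt(vnorm(u_lead), vnorm(u_free))
})

test_that("image flow at the source pushes away from the wall for a downward force", {
  for (mode in c("leading", "blake")) {
    src <- point_force(c(0, 0, 60), c(0, 0, -40))
    u_img <- image_system(src, src$position, FLUID, mode = mode)
    expect_gt(u_img[3], 0)
    expect_equal(u_img[1:2], c(0, 0), tolerance = 1e-14)
  }
  # leading-mode magnitude matches the f0/(8 pi mu l) back-flow scale at
  # separation 2h (longitudinal Oseen factor doubles it)
  h <- 60
  src <- point_force(c(0, 0, h), c(0, 0, -40))
  u_img <- image_system(src, src$position, FLUID, mode = "leading")
  expect_equal(u_img[3], 2 * 40 / (8 * pi * MU * 2 * h), tolerance = 1e-12)
})

test_that("ambient flow derivatives agree with finite differences", {
  set.seed(7)
  for (mode in c("leading", "blake")) {
    src <- point_force(c(5, -3, 50), c(10, -20, -35))
    x0 <- c(12, 4, 65)
    amb <- ambient_at(src, x0, FLUID, mode = mode)
    d <- 1e-3
    J <- matrix(0, 3, 3)
    for (l in 1:3) {
      e <- numeric(3); e[l] <- d
      J[, l] <- (image_system(src, x0 + e, FLUID, mode) -
                   image_system(src, x0 - e, FLUID, mode)) / (2 * d)
    }
    Om <- 0.5 * c(J[3, 2] - J[2, 3], J[1, 3] - J[3, 1], J[2, 1] - J[1, 2])
    E <- 0.5 * (J + t(J))
    scale <- max(abs(J))
    expect_lt(max(abs(amb$Omega - Om)) / scale, 1e-6)
    expect_lt(max(abs(amb$E - E)) / scale, 1e-6)
    # incompressibility
    expect_lt(abs(sum(diag(amb$E))) / scale, 1e-9)
  }
})

test_that("axisymmetric configuration gives axial ambient flow with no rotation", {
  src <- point_force(c(0, 0, 80), c(0, 0, -50))
  amb <- ambient_at(src, fluid = FLUID, mode = "leading")
  expect_equal(amb$u[1:2], c(0, 0), tolerance = 1e-14)
  expect_gt(amb$u[3], 0)
  expect_equal(amb$Omega, c(0, 0, 0), tolerance = 1e-14)
})

test_that("total field is numerically divergence-free in the bulk", {
  set.seed(11)
  for (mode in c("leading", "blake")) {
    src <- point_force(c(0, 0, 45), c(8, -12, -30))
    for (i in 1:5) {
      x0 <- c(runif(2, -80, 80), runif(1, 10, 120))
      d <- 1e-3
      div <- 0
      gradmax <- 0
      for (l in 1:3) {
        e <- numeric(3); e[l] <- d
        g <- (wall_velocity(src, x0 + e, FLUID, mode) -
                wall_velocity(src, x0 - e, FLUID, mode)) / (2 * d)
        div <- div + g[l]
        gradmax <- max(gradmax, max(abs(g)))
      }
      expect_lt(abs(div) / gradmax, 1e-6)
    }
  }
})

test_that("the wall-bounded field is linear in the applied force", {
  pos <- c(0, 0, 30)
  f1 <- c(5, 0, -20)
  f2 <- c(-3, 8, 12)
  x <- c(10, 10, 25)
  for (mode in c("leading", "blake")) {
    u_sum <- wall_velocity(point_force(pos, f1 + f2), x, FLUID, mode)
    expect_equal(u_sum,
                 wall_velocity(point_force(pos, f1), x, FLUID, mode) +
                   wall_velocity(point_force(pos, f2), x, FLUID, mode),
                 tolerance = 1e-12)
    expect_equal(wall_velocity(point_force(pos, 2 * f1), x, FLUID, mode),
                 2 * wall_velocity(point_force(pos, f1), x, FLUID, mode),
                 tolerance = 1e-12)
  }
})

test_that("far-field decay exponents separate stalked from wall-bound cells", {
  a <- 5
  # stalked: a << r << l, lateral sampling near the cell
  stalked <- point_force(c(0, 0, 2000), c(0, 0, -40))
  s1 <- radial_speed_sampler(stalked, elevation = pi / 6)
  expect_equal(decay_exponent(s1, 20, 200, 24), -1, tolerance = 0.1)
  # wall-height: r >> h = a
  grounded <- point_force(c(0, 0, a), c(0, 0, -40))
  s2 <- radial_speed_sampler(grounded, elevation = pi / 6)
  expect_equal(decay_exponent(s2, 50, 500, 24), -3, tolerance = 0.2)
  # free-space stokeslet decays exactly as 1/r
  src <- point_force(c(0, 0, 1e6), c(0, 0, -40))
  s3 <- function(r) vnorm(stokeslet(src, src$position + r * c(cos(0.5), 0, sin(0.5)),
                                    FLUID))
  expect_equal(decay_exponent(s3, 10, 100, 10), -1, tolerance = 1e-9)
  expect_error(decay_exponent(s3, 10, 100, 2), "3 samples")
})

test_that("tracer advection respects symmetry, reversibility and the field", {
  src <- point_force(c(0, 0, 100), c(0, 0, -40))
  # on-axis tracer stays on the axis
  tr <- advect_tracers(src, matrix(c(0, 0, 250), 1), dt = 0.05, duration = 2)
  expect_lt(max(abs(tr$x)), 1e-12)
  expect_lt(max(abs(tr$y)), 1e-12)
  expect_true(all(tr$z > 0))
  # Stokes reversibility: reverse the force, integrate the same time back
  start <- c(60, 0, 80)
  fwd <- advect_tracers(src, matrix(start, 1), dt = 0.01, duration = 1)
  endp <- unlist(fwd[nrow(fwd), c("x", "y", "z")])
  rev_src <- point_force(src$position, -src$force)
  back <- advect_tracers(rev_src, matrix(endp, 1), dt = 0.01, duration = 1)
  expect_equal(unname(unlist(back[nrow(back), c("x", "y", "z")])), start,
               tolerance = 1e-4)
  # step speed matches the analytic field to 1 %
  p1 <- unlist(fwd[2, c("x", "y", "z")])
  v_num <- (p1 - start) / 0.01
  v_ana <- wall_velocity(src, start, FLUID, "blake")
  expect_equal(vnorm(v_num - v_ana) / vnorm(v_ana), 0, tolerance = 0.01)
  expect_error(advect_tracers(src, matrix(src$position, 1), 0.1, 1), "singular")
})
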