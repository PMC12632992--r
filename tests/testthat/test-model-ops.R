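test_that("impingement rate matches its closed form and monotonicities", {
  mt <- mt_params(n_mt = 5000, v_g = 1, lambda = 0.038)
  motors <- motor_params(r = 1.5)
  # direct evaluation: 5000 * 0.038 * (1.5^2 / (4 * 100)) * exp(-0.38)
  expect_equal(impingement_rate(10, mt, motors),
               5000 * 0.038 * (2.25 / 400) * exp(-0.38), tolerance = 1e-12)
  expect_equal(round(impingement_rate(10, mt, motors), 3), 0.731)

  d <- seq(1, 60, by = 0.5)
  omega <- impingement_rate(d, mt, motors)
  expect_true(all(diff(omega) < 0))
  expect_lt(omega[length(omega)], 1e-2)

  # at large d (d * lambda / v_g >> 1) increasing lambda decreases Omega
  mt_hi <- mt_params(n_mt = 5000, v_g = 1, lambda = 0.08)
  expect_lt(impingement_rate(50, mt_hi, motors), impingement_rate(50, mt, motors))

  expect_error(impingement_rate(0, mt, motors), "d")
})

test_that("imposed chromosome separation follows the exponential law", {
  law <- chromosome_law()
  expect_identical(imposed_separation(0, law), 0)
  expect_equal(imposed_separation(1e6, law), 6.2)
  expect_equal(imposed_separation(29, law), 6.2 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(round(imposed_separation(29, law), 2), 3.92)
  t <- seq(0, 400, by = 0.5)
  expect_true(all(diff(imposed_separation(t, law)) >= 0))
  expect_true(all(imposed_separation(t, law) <= 6.2))
  expect_error(imposed_separation(-1, law), "t")
})

test_that("motor field decays by pure unbinding when no microtubules arrive", {
  mesh <- build_cell_mesh(7.3, 128)
  motors <- motor_params()
  # v_g so small that exp(-lambda d / v_g) underflows: Omega = 0 everywhere
  mt <- mt_params(v_g = 1e-8, lambda = 1)
  state <- spindle_state(0, c(0, 0, 2.7), c(0, 0, -2.7))
  field <- motor_field(mesh, P1 = rep(0.5, 128), P2 = rep(0.3, 128))
  dt <- 0.05
  for (i in 1:200) field <- evolve_motor_field(field, mesh, state, mt, motors, dt)
  # exact decay exp(-kappa t) vs first-order integrator, t = 10 s
  expect_equal(field$P1, rep(0.5 * (1 - motors$kappa * dt)^200, 128))
  expect_equal(mean(field$P1), 0.5 * exp(-motors$kappa * 10), tolerance = 1e-2)
})

test_that("motor field converges to the stoichiometric fixed point", {
  mesh <- build_cell_mesh(7.3, 256)
  motors <- motor_params()
  mt <- mt_params(lambda = 0.945)
  state <- spindle_state(0, c(0, 0, 2.7), c(0, 0, -2.7))
  d1 <- sqrt(rowSums(sweep(mesh$centers, 2, state$x1)^2))
  d2 <- sqrt(rowSums(sweep(mesh$centers, 2, state$x2)^2))
  o1 <- impingement_rate(d1, mt, motors)
  o2 <- impingement_rate(d2, mt, motors)

  field <- motor_field(mesh)
  # the explicit update shares its fixed point with the continuous dynamics,
  # so a large stable step converges there quickly
  for (i in 1:1200) field <- evolve_motor_field(field, mesh, state, mt, motors, 0.5)
  # steady state of dPi/dt = Omega_i (1 - P1 - P2) - kappa Pi:
  # P_i* = Omega_i / (Omega_1 + Omega_2 + kappa)
  expect_equal(field$P1, o1 / (o1 + o2 + motors$kappa), tolerance = 1e-6)
  expect_equal(field$P2, o2 / (o2 + o1 + motors$kappa), tolerance = 1e-6)
  # with equal rates the fixed point reduces to Omega/(2 Omega + kappa); on
  # this symmetric configuration each patch and its antipode form such a pair
  expect_equal(field$P1, field$P2[c(129:256, 1:128)], tolerance = 1e-9)
})

test_that("unstable field time steps are rejected naming dt", {
  mesh <- build_cell_mesh(7.3, 128)
  motors <- motor_params()
  mt <- mt_params(lambda = 0.945)
  # pole very close to the cortex: Omega is large there
  state <- spindle_state(0, c(0, 0, 6.9), c(0, 0, -6.9))
  field <- motor_field(mesh)
  expect_error(evolve_motor_field(field, mesh, state, mt, motors, 0.5), "dt = 0.5")
})

test_that("cortical force is zero by symmetry at the center", {
  mesh <- build_cell_mesh(10, 2000)
  motors <- motor_params()
  field <- motor_field(mesh, P1 = rep(0.5, nrow(mesh$centers)))
  f <- cortical_force(field, mesh, c(0, 0, 0), 1, motors)
  m <- motor_count(motors, 10)
  expect_lt(sqrt(sum(f^2)), 1e-6 * m * motors$f0)
})

test_that("single-occupied-patch force equals the single-term sum", {
  mesh <- build_cell_mesh(10, 512)
  motors <- motor_params()
  n <- nrow(mesh$centers)
  P1 <- rep(0, n)
  P1[37] <- 1
  field <- motor_field(mesh, P1 = P1)
  pole <- c(1, -2, 3)
  xi <- mesh$centers[37, ] - pole
  xi <- xi / sqrt(sum(xi^2))
  m <- motor_count(motors, 10)
  expected <- (m * motors$f0 / (4 * pi * 100)) * mesh$areas[37] * xi
  expect_equal(cortical_force(field, mesh, pole, 1, motors), expected,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("uniform-field force on a displaced pole matches the brute-force integral", {
  motors <- motor_params()
  radius <- 10
  mesh <- build_cell_mesh(radius, 8000)
  field <- motor_field(mesh, P1 = rep(1, nrow(mesh$centers)))
  for (a in c(2, 5, 8)) {
    f <- cortical_force(field, mesh, c(0, 0, a), 1, motors)
    expect_equal(unname(f[3]), uniform_force_z_oracle(a, radius, motors),
                 tolerance = 1e-3)
    expect_lt(sqrt(sum(f[1:2]^2)), 1e-3 * abs(f[3]))
  }
  # the uniform field pulls a displaced pole back toward the bulk of the
  # surface, i.e. toward the cell center: a restoring force
  f <- cortical_force(field, mesh, c(0, 0, 5), 1, motors)
  expect_lt(f[3], 0)
})

test_that("pole on or outside the surface is rejected", {
  mesh <- build_cell_mesh(10, 256)
  field <- motor_field(mesh)
  expect_error(cortical_force(field, mesh, c(0, 0, 10), 1, motor_params()), "outside")
})

test_that("pole update reduces to F/eta when the viscous coupling vanishes", {
  drags <- drag_params(eta = 450, nu = 0)
  law <- chromosome_law()
  state <- spindle_state(0, c(0, 0, 5), c(0, 0, -5), law)
  dt <- 0.01
  upd <- step_state(state, c(0, 0, 45), c(0, 0, -45), drags, law, dt)
  # velocity F / eta = 0.1 um/s, exactly, at a single step
  expect_identical(upd$x1[3], 5 + dt * 0.1)
  expect_identical(upd$x2[3], -5 - dt * 0.1)
})

test_that("chromosome motion drags the poles through the viscous element", {
  # dDc/dt = c_f / tau_c = 0.2 um/s at t = 0, so each plate moves at 0.1;
  # with F = 0: parallel velocity = nu * 0.1 / (eta + nu) = 0.01 um/s
  law <- chromosome_law(c_f = 5.8, tau_c = 29)
  drags <- drag_params(eta = 450, nu = 50)
  state <- spindle_state(0, c(0, 0, 5), c(0, 0, -5), law)
  dt <- 0.001
  upd <- step_state(state, c(0, 0, 0), c(0, 0, 0), drags, law, dt)
  expect_equal(upd$x1[3], 5 + dt * 0.01, tolerance = 1e-12)
  expect_equal(upd$x2[3], -5 - dt * 0.01, tolerance = 1e-12)
})

test_that("perpendicular forces are independent of the viscous coupling", {
  law <- chromosome_law()
  state <- spindle_state(0, c(0, 0, 5), c(0, 0, -5), law)
  f_perp <- c(9, 0, 0)
  dt <- 0.01
  for (nu in c(0, 50, 500)) {
    upd <- step_state(state, f_perp, f_perp, drag_params(eta = 450, nu = nu),
                      law, dt)
    expect_equal(upd$x1[1], dt * 9 / 450, tolerance = 1e-12)
  }
})

test_that("coincident poles are rejected", {
  expect_error(spindle_state(0, c(0, 0, 1), c(0, 0, 1)), "coincide")
})
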