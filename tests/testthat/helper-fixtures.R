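# Shared fixtures for the test suite. Simulations in unit tests run at
# reduced resolution (small meshes, short horizons); the acceptance tests use
# the full defaults where the criterion requires them.

stage64 <- function() stage_config(64, cell_radius = 7.3, initial_d_pp = 5.4,
                                   lambda = 0.945)
stage8 <- function() stage_config(8, cell_radius = 14, initial_d_pp = 9,
                                  lambda = 0.164)

# evaluate the sigmoid / exponential models directly
sigmoid_val <- function(t, L1, L2, t0, tau_s) L1 + L2 / (1 + exp(-(t - t0) / tau_s))
exp_val <- function(t, a, k) a * (1 - exp(-t / k))

# brute-force oracle for the uniform-field cortical force: reduce the surface
# integral (M f0 / A) * Int xi_hat dA for a pole at (0, 0, a) to a 1-D
# quadrature in the polar angle and evaluate it with stats::integrate
uniform_force_z_oracle <- function(a, radius, motors) {
  integrand <- function(theta) {
    dz <- radius * cos(theta) - a
    dist <- sqrt(radius^2 + a^2 - 2 * a * radius * cos(theta))
    sin(theta) * dz / dist
  }
  m <- motor_count(motors, radius)
  area <- 4 * pi * radius^2
  (m * motors$f0 / area) * 2 * pi * radius^2 *
    stats::integrate(integrand, 0, pi, rel.tol = 1e-10)$value
}
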