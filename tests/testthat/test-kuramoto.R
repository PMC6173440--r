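test_that("delays are proportional to lengths with the mean-delay pivot", {
  sc <- toy_connectome(n_nodes = 20, seed = 6)
  cfg <- kuramoto_config(coupling = 1, mean_delay_ms = 12, dt_ms = 0.2,
                         duration_s = 21)
  del <- build_delays(sc, cfg)
  conn <- sc$weights > 0
  lbar <- mean(sc$lengths[conn])
  # the edge at the mean length gets exactly the mean delay
  expect_equal(mean(del$delays_ms[conn]), 12, tolerance = 1e-12)
  expect_equal(del$delays_ms[conn], sc$lengths[conn] / lbar * 12,
               tolerance = 1e-12)
  # mean fiber length 84.5 mm at 12 ms / 2 ms mean delay: printed velocities
  expect_lt(abs((84.5 / 1000) / (12 / 1000) - 7.0), 0.05)
  expect_lt(abs((84.5 / 1000) / (2 / 1000) - 42.3), 0.05)
  # doubling lengths at fixed velocity doubles delays
  sc2 <- sc; sc2$lengths <- sc$lengths * 2
  cfgv <- kuramoto_config(coupling = 1, conduction_velocity_m_s = 8,
                          duration_s = 21)
  expect_equal(build_delays(sc2, cfgv)$delays_ms,
               2 * build_delays(sc, cfgv)$delays_ms)
  # delay steps at least one on every edge
  expect_true(all(del$delay_steps[conn] >= 1))
  expect_error(kuramoto_config(coupling = 1, duration_s = 30),
               "exactly one")
  expect_error(kuramoto_config(coupling = 1, mean_delay_ms = 5,
                               conduction_velocity_m_s = 5,
                               duration_s = 30),
               "exactly one")
})

test_that("uncoupled oscillators rotate at the natural frequency exactly", {
  sc <- toy_connectome(n_nodes = 15, seed = 8)
  cfg <- kuramoto_config(coupling = 0, mean_delay_ms = 10, dt_ms = 1,
                         duration_s = 21, transient_discard_s = 20,
                         seed = 77)
  th <- simulate_kuramoto(sc, cfg)$phases
  set.seed(77)
  init <- stats::runif(15, 0, 2 * pi)
  tt <- 20 + seq_len(ncol(th)) * 0.001
  for (n in c(1, 7, 15)) {
    expected <- (init[n] + 2 * pi * 60 * tt) %% (2 * pi)
    err <- abs(expected - th[n, ])
    expect_lt(max(pmin(err, 2 * pi - err)), 1e-8)
  }
  expect_true(all(th >= 0 & th < 2 * pi))
})

test_that("two coupled oscillators relax like the phase-difference ODE", {
  # symmetric dyad: Delta = theta1 - theta2 obeys dDelta/dt = -2 k C sin(Delta);
  # oracle: dense Runge-Kutta solution via deSolve on the 1-D reduced equation
  skip_if_not_installed("deSolve")
  w <- matrix(c(0, 1, 1, 0), 2)
  l <- matrix(c(0, 1e-4, 1e-4, 0), 2)     # negligible delay (1 step at dt)
  sc <- structural_connectome(w, l)
  k <- 2
  dt_ms <- 0.01
  cfg <- kuramoto_config(coupling = k, conduction_velocity_m_s = 10,
                         natural_frequency_hz = 60, dt_ms = dt_ms,
                         noise_sd_rad_s = 0, duration_s = 1.2,
                         transient_discard_s = 0, seed = 12)
  th <- simulate_kuramoto(sc, cfg)$phases
  delta <- apply(th, 2, function(col) {
    d <- (col[1] - col[2]) %% (2 * pi)
    if (d > pi) d - 2 * pi else d
  })
  set.seed(12)
  d0 <- diff(rev(stats::runif(2, 0, 2 * pi)))
  d0 <- ((d0 + pi) %% (2 * pi)) - pi
  times <- seq_len(ncol(th)) * dt_ms / 1000
  sol <- deSolve::ode(y = c(d = d0), times = c(0, times), parms = NULL,
                      func = function(t, y, p) list(-2 * k * sin(y)),
                      method = "ode45")
  expect_lt(max(abs(sol[-1, "d"] - delta)), 1e-3)
  # the difference decays toward phase lock
  expect_lt(abs(delta[length(delta)]), abs(d0) * 0.2 + 1e-6)
})

test_that("stochastic integration is reproducible and seed-sensitive", {
  sc <- toy_connectome(n_nodes = 12, seed = 9)
  cfg <- kuramoto_config(coupling = 5, mean_delay_ms = 8, dt_ms = 1,
                         noise_sd_rad_s = 1.25, duration_s = 22,
                         transient_discard_s = 20, seed = 123)
  a <- simulate_kuramoto(sc, cfg)
  b <- simulate_kuramoto(sc, cfg)
  expect_identical(a$phases, b$phases)
  cfg2 <- cfg; cfg2$seed <- 124
  expect_false(identical(simulate_kuramoto(sc, cfg2)$phases, a$phases))
  expect_true(all(is.finite(a$phases)))
})

test_that("order parameter matches its closed-form cases", {
  # identical phases: full coherence, zero metastability
  op1 <- order_parameter(matrix(1.3, 5, 100))
  expect_equal(op1$magnitude, rep(1, 100))
  expect_equal(op1$synchrony, 1)
  expect_equal(op1$metastability, 0)
  # equally spaced phases cancel
  n <- 8
  op0 <- order_parameter(matrix(2 * pi * (0:(n - 1)) / n, n, 3))
  expect_lt(max(op0$magnitude), 1e-12)
  # iid uniform phases: R of order 1/sqrt(N)
  set.seed(42)
  mags <- replicate(200, order_parameter(
    matrix(stats::runif(1000, 0, 2 * pi), 1000, 1))$synchrony)
  expect_gt(mean(mags < 0.1), 0.99)
})

test_that("synchrony does not decrease with coupling on a zero-delay complete graph", {
  n <- 10
  w <- matrix(1 / n, n, n); diag(w) <- 0
  l <- matrix(1e-4, n, n); diag(l) <- 0
  sc <- structural_connectome(w, l)
  syn <- vapply(c(0.5, 5, 50), function(k) {
    cfg <- kuramoto_config(coupling = k, conduction_velocity_m_s = 10,
                           dt_ms = 0.1, duration_s = 3,
                           transient_discard_s = 2, seed = 4)
    order_parameter(simulate_kuramoto(sc, cfg))$synchrony
  }, numeric(1))
  expect_true(all(diff(syn) >= -1e-6))
  expect_gt(syn[3], 0.99)   # strong coupling locks the ensemble
})
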