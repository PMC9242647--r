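# Occupancy model: closed-form checks against an independent ODE
# integration, continuity, invariants, and the shipped orderings.

test_that("occupancy is 1 before stress and decays to the floor", {
  m <- default_kinetic_model()
  expect_equal(simulate_occupancy(m, "PIP2", c(0, 300, 599)), rep(1, 3))
  # t -> infinity with no reoxygenation: push t_reoxy out, evaluate late
  m2 <- kinetic_model(600, 1e7, sensors = m$sensors)
  expect_equal(simulate_occupancy(m2, "PIP2", 5e6),
               m$sensors$PIP2$floor, tolerance = 1e-8)
  expect_error(simulate_occupancy(m, "nosuch", 0), "unknown sensor")
})

test_that("closed-form decay matches numeric integration of the decay ODE", {
  m <- kinetic_model(0, 1e6, sensors = list(
    s = sensor_kinetics(depletion_delay = 0, depletion_rate = 0.002,
                        floor = 0.1)))
  got <- simulate_occupancy(m, "s", 500)
  expect_equal(got, 0.1 + 0.9 * exp(-1), tolerance = 1e-9)
  # independent oracle: forward-Euler integration of f' = -k (f - floor)
  f <- 1; dt <- 0.001
  for (i in seq_len(500 / dt)) f <- f - dt * 0.002 * (f - 0.1)
  expect_equal(got, f, tolerance = 1e-3)
  expect_equal(got, 0.431, tolerance = 1e-3)
})

test_that("occupancy is continuous everywhere, overshoot included", {
  m <- default_kinetic_model()
  t <- seq(0, 5400, by = 0.5)
  for (s in names(m$sensors)) {
    f <- simulate_occupancy(m, s, t)
    expect_true(all(is.finite(f)), info = s)
    expect_lt(max(abs(diff(f))), 0.01)
    a <- m$sensors[[s]]$overshoot_amp
    expect_true(all(f >= 0 & f <= 1 + a + 1e-9), info = s)
  }
  # overshoot pulse really rises above baseline and decays again
  f4 <- simulate_occupancy(m, "PI4P", t)
  expect_gt(max(f4), 1.05)
  expect_lt(f4[t == 1080], max(f4))
})

test_that("constructor enforces the model invariants", {
  expect_error(sensor_kinetics(floor = 0.5, plateau = 0.4), "floor")
  expect_error(sensor_kinetics(depletion_rate = -1), ">= 0")
  expect_error(sensor_kinetics(plateau = 1.2), "floor")   # > 1 + overshoot
  expect_error(kinetic_model(100, 100, sensors = list(a = sensor_kinetics())),
               "t_hypoxia")
  expect_error(kinetic_model(0, 10, sensors = list(sensor_kinetics())), "named")
})

test_that("shipped defaults order depletion Lgl < PIP2 < PI4P and recovery PI4P < PIP2 < Lgl", {
  m <- default_kinetic_model()
  dep <- vapply(c("Lgl", "PIP2", "PI4P"),
                function(s) occupancy_halftime(m, s, "depletion"), numeric(1))
  rec <- vapply(c("PI4P", "PIP2", "Lgl"),
                function(s) occupancy_halftime(m, s, "recovery"), numeric(1))
  expect_true(all(diff(dep) > 0))
  expect_true(all(diff(rec) > 0))
  # recovery completes on the ~10 min scale
  expect_true(all(rec - m$t_reoxy < 600))
})

test_that("puncta pool empties before PM PI4P and refills after it", {
  m <- default_kinetic_model()
  t <- seq(0, 5400, by = 10)
  pm <- simulate_occupancy(m, "PI4P", t)
  pu <- simulate_occupancy(m, "PI4P", t, pool = "puncta")
  half_cross <- function(f) t[which(f < (1 + min(f)) / 2)[1]]
  expect_lt(half_cross(pu), half_cross(pm))
  rec_cross <- function(f) {
    post <- t > m$t_reoxy
    t[post][which(f[post] > 0.75)[1]]
  }
  expect_gt(rec_cross(pu), rec_cross(pm))
})

test_that("increasing depletion_rate strictly decreases the half-depletion time", {
  rates <- c(0.001, 0.002, 0.004, 0.008)
  t50 <- vapply(rates, function(r) {
    m <- kinetic_model(600, 3600, sensors = list(
      s = sensor_kinetics(depletion_delay = 120, depletion_rate = r, floor = 0.05)))
    occupancy_halftime(m, "s", "depletion")
  }, numeric(1))
  expect_true(all(diff(t50) < 0))
})
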