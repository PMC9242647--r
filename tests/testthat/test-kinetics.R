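# Kinetics fitting and between-sensor ordering statistics.

test_that("noiseless series recover the generator parameters within 1%", {
  m <- default_kinetic_model()
  for (sensor in c("PIP2", "Lgl")) {  # no overshoot: fit model matches
    s <- simulate_index_series(m, sensor, noise_sd = 0, seed = 1)
    fit <- fit_kinetics(s$time_s, s$value, m$t_hypoxia, m$t_reoxy)
    p <- m$sensors[[sensor]]
    expect_true(fit$converged)
    expect_equal(unname(fit$par["baseline"]), 1, tolerance = 0.01)
    expect_lt(abs(fit$par[["depletion_rate"]] - p$depletion_rate),
              0.01 * p$depletion_rate)
    expect_lt(abs(fit$par[["floor"]] - p$floor), 0.01)
    expect_lt(abs(fit$par[["plateau"]] - p$plateau), 0.01)
    expect_lt(abs(fit$par[["delay"]] - p$depletion_delay),
              0.01 * p$depletion_delay + 1)
    t50_true <- occupancy_halftime(m, sensor, "depletion")
    expect_equal(fit$t50_dep, t50_true, tolerance = 0.01 * t50_true)
    t50r_true <- occupancy_halftime(m, sensor, "recovery")
    expect_equal(fit$t50_rec, t50r_true, tolerance = 0.01 * t50r_true)
  }
})

test_that("noisy series recover t50 within 10% median absolute error", {
  m <- default_kinetic_model()
  t50_true <- occupancy_halftime(m, "PIP2", "depletion") - m$t_hypoxia
  t50r_true <- occupancy_halftime(m, "PIP2", "recovery") - m$t_reoxy
  errs <- sapply(1:20, function(i) {
    s <- simulate_index_series(m, "PIP2", noise_sd = 0.05, seed = 100 + i)
    fit <- fit_kinetics(s$time_s, s$value, m$t_hypoxia, m$t_reoxy)
    c(abs(fit$t50_dep - m$t_hypoxia - t50_true) / t50_true,
      abs(fit$t50_rec - m$t_reoxy - t50r_true) / t50r_true)
  })
  expect_lt(median(errs[1, ]), 0.10)
  expect_lt(median(errs[2, ]), 0.10)
})

test_that("constant series are flagged with zero rate and undefined t50", {
  t <- 0:89 * 60
  fit <- fit_kinetics(t, rep(1, 90), 600, 3600)
  expect_true(fit$flagged)
  expect_equal(unname(fit$par["depletion_rate"]), 0)
  expect_true(is.na(fit$t50_dep) && is.na(fit$t50_rec))
  expect_error(fit_kinetics(t[1:8], rep(1, 8), 600, 3600), ">= 5")
})

test_that("parameter recovery degrades monotonically with noise", {
  m <- default_kinetic_model()
  t50_true <- occupancy_halftime(m, "PIP2", "depletion")
  mae <- sapply(c(0.03, 0.12, 0.5), function(sd) {
    errs <- sapply(1:12, function(i) {
      s <- simulate_index_series(m, "PIP2", noise_sd = sd, seed = 300 + i)
      fit <- fit_kinetics(s$time_s, s$value, m$t_hypoxia, m$t_reoxy)
      abs(fit$t50_dep - t50_true)
    })
    median(errs, na.rm = TRUE)
  })
  expect_true(all(diff(mae) > 0))
})

test_that("compare_onsets: identity, antisymmetry, pairing errors", {
  m <- default_kinetic_model()
  fits <- lapply(1:8, function(i) {
    s <- simulate_index_series(m, "PIP2", noise_sd = 0.05, seed = 400 + i)
    fit_kinetics(s$time_s, s$value, m$t_hypoxia, m$t_reoxy)
  })
  same <- compare_onsets(fits, fits, "depletion", n_boot = 200, seed = 1)
  expect_equal(same$median, 0)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)
  fits_b <- lapply(1:8, function(i) {
    s <- simulate_index_series(m, "PI4P", noise_sd = 0.05, seed = 500 + i)
    fit_kinetics(s$time_s, s$value, m$t_hypoxia, m$t_reoxy)
  })
  ab <- compare_onsets(fits, fits_b, "depletion", n_boot = 200, seed = 2)
  ba <- compare_onsets(fits_b, fits, "depletion", n_boot = 200, seed = 2)
  expect_equal(ab$median, -ba$median)
  expect_lt(ab$median, 0)  # PIP2 depletes first
  expect_error(compare_onsets(fits, fits_b[1:5], "depletion"), "paired")
  # deterministic for a fixed seed
  ab2 <- compare_onsets(fits, fits_b, "depletion", n_boot = 200, seed = 2)
  expect_identical(ab$ci, ab2$ci)
})

test_that("analytic SSE gradient matches central finite differences", {
  set.seed(900)
  t <- 0:89 * 60
  m <- default_kinetic_model()
  vals <- simulate_occupancy(m, "PIP2", t) + rnorm(90, 0, 0.05)
  obj <- function(p) sum((vals - pmindex:::kinetics_curve(p, t, 600, 3600))^2)
  for (i in 1:10) {
    p <- c(runif(1, 0.5, 1.5), runif(1, 0, 1000), runif(1, 1e-4, 0.02),
           runif(1, 0, 0.5), runif(1, 10, 600), runif(1, 1e-4, 0.02),
           runif(1, 0.5, 1.5))
    g <- pmindex:::kinetics_sse_grad(p, t, vals, 600, 3600)
    gn <- sapply(1:7, function(j) {
      h <- pmax(abs(p[j]), 1) * 1e-6
      pp <- p; pm <- p; pp[j] <- p[j] + h; pm[j] <- p[j] - h
      (obj(pp) - obj(pm)) / (2 * h)
    })
    expect_lt(max(abs(g - gn) / (abs(gn) + 1e-6)), 1e-4)
  }
})
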