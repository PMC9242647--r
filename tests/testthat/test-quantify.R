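# PM index arithmetic, series measurement, normalization conventions.

test_that("pm_index follows the background-corrected ratio", {
  expect_equal(pm_index(100, 50, 10), 2.25)
  # pm == cyto gives 1 regardless of background
  expect_equal(pm_index(80, 80, 7), 1)
  expect_equal(pm_index(80, 80, 53), 1)
  expect_error(pm_index(100, 10, 10), "undefined")
})

test_that("a static noiseless stack yields a constant series equal to truth", {
  g <- generate_geometry(4, c(96, 96), "tissue", seed = 2)
  m <- kinetic_model(1e5, 2e5, sensors = default_kinetic_model()$sensors)
  r <- render_stack(g, m, channels = c("PIP2", "dye"), n_frames = 6,
                    noise = list(gain = 0, read_sigma = 0),
                    drift = list(step_sigma = 0), seed = 1)
  rois <- synthetic_rois(g, n = 2, seed = 3)
  masks <- segment_stack(r$stack, rois, method = "mean", mask_channel = "dye")
  s <- pm_index_series(r$stack, masks, rois[[1]], "PIP2")
  expect_true(all(s$valid))
  expect_equal(length(unique(round(s$pm_index, 9))), 1)
  tr <- r$truth$cells
  cells <- attr(rois, "cells")[[1]]
  tru <- mean(tr$true_pm_index[tr$frame == 1 & tr$channel == "PIP2" &
                                 tr$cell %in% cells])
  # background rule (noiseless min = rendered offset) makes this exact up to
  # the pixel mix of the two cells sharing the junction ROI, whose densities
  # differ with cell size; the per-cell identity is tested in synthetic-data
  expect_equal(s$pm_index[1], tru, tolerance = 0.10)
})

test_that("full time-course series falls after stress and rises after reoxygenation", {
  fix <- small_sim()
  res <- quantify_stack(fix$sim$stack, synthetic_rois(fix$geom, n = 2, seed = 5),
                        channels = "PIP2")
  s <- res$series[[1]]
  m <- fix$model
  pre <- mean(s$pm_index[s$time_s <= m$t_hypoxia])
  floor_phase <- mean(s$pm_index[s$time_s > m$t_reoxy - 300 & s$time_s <= m$t_reoxy])
  post <- mean(s$pm_index[s$time_s > max(s$time_s) - 300])
  expect_gt(pre, 2 * floor_phase)
  expect_gt(post, 2 * floor_phase)
})

test_that("saturated frames are flagged invalid without poisoning neighbors", {
  g <- generate_geometry(4, c(96, 96), "tissue", seed = 2)
  m <- small_model()
  r <- render_stack(g, m, channels = c("PIP2", "dye"), n_frames = 5,
                    noise = list(gain = 0, read_sigma = 0),
                    drift = list(step_sigma = 0), seed = 1)
  st <- r$stack
  st$bit_depth <- 12
  st$data[3, 1, , ] <- 4095  # everything at the saturation cap
  rois <- synthetic_rois(g, n = 1, seed = 3)
  masks <- segment_stack(st, rois, method = "mean", mask_channel = "dye")
  s <- pm_index_series(st, masks, rois[[1]], "PIP2")
  expect_false(s$valid[3])
  expect_equal(s$sat_frac[3], 1)
  expect_true(all(s$valid[-3]))
  expect_true(all(is.finite(s$pm_index[-3])))
})

test_that("normalization conventions, baseline, idempotence and errors", {
  s <- structure(
    data.frame(frame = 1:6, time_s = 0:5 * 60,
               pm_mean = c(90, 92, 91, 60, 40, 30),
               cyto_mean = rep(40, 6), background = rep(10, 6),
               pm_index = c(11 / 3, 41 / 15, 2.7, 5 / 3, 1, 2 / 3) + 0,
               n_pm_px = 10L, n_cyto_px = 20L, sat_frac = 0, valid = TRUE),
    roi = "r1", channel = "PIP2", class = c("pm_index_series", "data.frame"))
  s$pm_index <- (s$pm_mean - s$background) / (s$cyto_mean - s$background)
  n <- normalize_series(s, baseline_n = 3)
  base <- mean(s$pm_index[1:3] - 1)
  expect_equal(n$norm_pm_index, (s$pm_index - 1) / base)
  expect_equal(mean(n$norm_pm_index[1:3]), 1)
  # PMI = 1 (fully cytosolic) maps to 0
  expect_equal(n$norm_pm_index[s$pm_index == 1], 0)
  # idempotence: a normalized series is returned unchanged
  expect_identical(normalize_series(n, baseline_n = 3), n)
  # plain convention divides the index itself
  p <- normalize_series(s, baseline_n = 2, convention = "plain")
  expect_equal(p$norm_pm_index, s$pm_index / mean(s$pm_index[1:2]))
  # baseline ~ 1 errors, naming the ROI
  flat <- s; flat$pm_index <- rep(1, 6)
  expect_error(normalize_series(flat), "r1")
  expect_error(normalize_series(s, baseline_n = 0), "baseline_n")
})

test_that("cyto intensity series is 1 for a static stack and offset-cancelling", {
  g <- generate_geometry(4, c(96, 96), "tissue", seed = 2)
  m <- kinetic_model(1e5, 2e5, sensors = default_kinetic_model()$sensors)
  r <- render_stack(g, m, channels = c("ATP", "dye"), n_frames = 6,
                    noise = list(gain = 0, read_sigma = 0),
                    drift = list(step_sigma = 0), seed = 1)
  rois <- synthetic_rois(g, n = 1, seed = 3)
  masks <- segment_stack(r$stack, rois, method = "mean", mask_channel = "dye")
  s <- cyto_intensity_series(r$stack, masks, rois[[1]], "ATP")
  expect_equal(s$cyto_index, rep(1, 6), tolerance = 1e-9)
  # constant offset cancels through background subtraction (method = min
  # captures the offset exactly on this noiseless stack)
  st2 <- r$stack; st2$data <- st2$data + 55
  masks2 <- segment_stack(st2, rois, method = "mean", mask_channel = "dye")
  s2 <- cyto_intensity_series(st2, masks2, rois[[1]], "ATP")
  expect_equal(s2$cyto_index, s$cyto_index, tolerance = 1e-9)
})

test_that("ATP channel under inhibition drops and recovers with the right half-time", {
  g <- generate_geometry(4, c(96, 96), "tissue", seed = 2)
  m <- small_model()
  r <- render_stack(g, m, channels = c("ATP", "dye"), n_frames = 40,
                    noise = list(gain = 2, read_sigma = 2),
                    drift = list(step_sigma = 0), seed = 7)
  rois <- synthetic_rois(g, n = 1, seed = 3)
  work <- denoise(r$stack, gain = 2, read_sigma = 2)
  masks <- segment_stack(work, rois, method = "mean", mask_channel = "dye")
  s <- cyto_intensity_series(r$stack, masks, rois[[1]], "ATP",
                             background_method = "percentile")
  occ <- simulate_occupancy(m, "ATP", s$time_s)
  half <- (1 + min(occ)) / 2
  t_true <- which(occ < half)[1]
  t_meas <- which(s$cyto_index < half)[1]
  expect_lte(abs(t_meas - t_true), 2)
  expect_gt(mean(s$cyto_index[35:40]), 0.75)  # recovery
})
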