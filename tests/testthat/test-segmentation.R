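# PM/cytosol masks, background detection, exclusion detection.

two_level_frame <- function() {
  img <- matrix(10, 32, 32)
  img[, 17:32] <- 30
  img
}

test_that("mean-threshold mask selects the bright half of a two-level ROI", {
  img <- two_level_frame()
  roi <- rect_roi(8, 8, 16, 16)
  pm <- mean_threshold_pm_mask(img, roi)
  rm <- rasterize_roi(roi, dim(img))
  expect_equal(attr(pm, "threshold"), 20)
  expect_true(all(img[pm] == 30))
  expect_equal(sum(pm), sum(rm & img == 30))
  # affine rescaling a*I + b (a > 0) leaves the mask unchanged
  pm2 <- mean_threshold_pm_mask(3.7 * img + 11, roi)
  expect_equal(pm2, pm, ignore_attr = TRUE)
})

test_that("constant ROI yields the whole ROI with a warning", {
  img <- matrix(5, 32, 32)
  roi <- rect_roi(4, 4, 10, 10)
  expect_warning(pm <- mean_threshold_pm_mask(img, roi), "constant ROI")
  expect_equal(sum(pm), 100)
  expect_error(mean_threshold_pm_mask(matrix(NA_real_, 32, 32), roi), "finite")
})

test_that("mean-threshold mask captures a Gaussian membrane ridge (Dice >= 0.7)", {
  h <- 48; w <- 48
  gr <- matrix(seq_len(h), h, w)
  ridge <- 80 * exp(-(gr - 24)^2 / (2 * 1.5^2)) + 20
  band <- abs(gr - 24) <= 2
  roi <- rect_roi(4, 4, 40, 40)
  pm <- mean_threshold_pm_mask(ridge, roi)
  rm <- rasterize_roi(roi, c(h, w))
  dice <- 2 * sum(pm & band & rm) / (sum(pm) + sum(band & rm))
  expect_gte(dice, 0.7)
  expect_true(all(which(pm) %in% which(rm)))
})

test_that("cytosol mask complements the PM mask with guard ring and exclusions", {
  img <- two_level_frame()
  roi <- rect_roi(8, 8, 16, 16)
  pm <- mean_threshold_pm_mask(img, roi)
  cy <- cytosol_mask(img, roi, pm, guard_px = 0)
  expect_true(all(img[cy] == 10))
  expect_false(any(cy & pm))
  # guard ring removes the pixels adjacent to the PM mask
  cy1 <- cytosol_mask(img, roi, pm, guard_px = 1)
  expect_lt(sum(cy1), sum(cy))
  expect_false(any(cy1 & pmindex:::dilate_disk(pm, 1)))
  # exclusions covering all sub-threshold pixels leave nothing: error
  excl <- rasterize_roi(roi, dim(img)) & img < 20
  expect_error(cytosol_mask(img, roi, pm, exclusions = excl), "enlarge")
  expect_error(cytosol_mask(img, roi, pm | !rasterize_roi(roi, dim(img))),
               "outside")
})

test_that("wavelet PM mask finds the membrane of a clean synthetic cell (Dice >= 0.8)", {
  g <- generate_geometry(1, c(96, 96), "single_cell", seed = 13)
  m <- small_model()
  r <- render_stack(g, m, channels = "dye", n_frames = 2,
                    noise = list(gain = 0, read_sigma = 0),
                    drift = list(step_sigma = 0), seed = 1)
  set.seed(99)
  frame <- r$stack$data[1, 1, , ] +
    matrix(rnorm(96 * 96, 0, 0.5), 96)  # tiny noise so MAD sigma > 0
  # ROI per the drawing protocol: covers PM and cytoplasm, avoids the nucleus
  cell <- which(g$cell_label_image == 1, arr.ind = TRUE)
  nuc <- which(g$nuclei_mask, arr.ind = TRUE)
  roi <- roi_spec("strip", rbind(
    c(min(cell[, 1]) - 4, min(cell[, 2]) - 4),
    c(min(cell[, 1]) - 4, min(nuc[, 2]) - 3),
    c(max(cell[, 1]) + 4, min(nuc[, 2]) - 3),
    c(max(cell[, 1]) + 4, min(cell[, 2]) - 4)), kind = "cell_region")
  pm <- wavelet_pm_mask(frame, roi, levels_used = c(2, 3), k_sigma = 3)
  band <- g$membrane_mask & rasterize_roi(roi, c(96, 96))
  dice <- 2 * sum(pm & band) / (sum(pm) + sum(band))
  expect_gte(dice, 0.8)
  # adding a constant offset leaves the mask identical
  pm2 <- wavelet_pm_mask(frame + 500, roi, levels_used = c(2, 3), k_sigma = 3)
  expect_equal(pm2, pm, ignore_attr = TRUE)
})

test_that("wavelet mask false-positive area on pure noise is <= 0.1% at k = 6", {
  set.seed(44)
  roi <- rect_roi(4, 4, 88, 88)
  frac <- replicate(50, {
    img <- matrix(rnorm(96 * 96, 100, 10), 96)
    pm <- tryCatch(wavelet_pm_mask(img, roi, k_sigma = 6),
                   error = function(e) matrix(FALSE, 96, 96))
    sum(pm) / sum(rasterize_roi(roi, c(96, 96)))
  })
  expect_lte(mean(frac), 0.001)
})

test_that("background detection follows the minimum rule and percentile option", {
  img <- matrix(runif(100, 5, 50), 10)
  img[4, 7] <- 0
  expect_equal(detect_background(img, "min"), 0)
  expect_equal(detect_background(matrix(7, 5, 5), "min"), 7)
  expect_equal(detect_background(matrix(7, 5, 5), "percentile", p = 0.5), 7)
  # known read-noise floor: percentile lands within 2 sigma of truth
  set.seed(45)
  bg <- 12; sig <- 2
  frame <- matrix(bg + rnorm(128 * 128, 0, sig), 128)
  frame[40:90, 40:90] <- 200  # bright object
  est <- detect_background(denoise(frame, gain = 0.01, read_sigma = sig),
                           "percentile", p = 0.1)
  expect_lt(abs(est - bg), 2 * sig)
})

test_that("exclusion detection finds puncta and nuclei and is offset-invariant", {
  g <- generate_geometry(1, c(96, 96), "single_cell", seed = 14, n_puncta = 5)
  m <- small_model()
  r <- render_stack(g, m, channels = "PI4P", n_frames = 2,
                    noise = list(gain = 1, read_sigma = 1),
                    drift = list(step_sigma = 0), seed = 2,
                    amplitudes = c(PI4P = 100))
  frame <- r$stack$data[1, 1, , ]
  roi_mask <- g$cell_label_image == 1
  ex <- detect_exclusions(frame, roi_mask)
  hits <- sum(ex[cbind(g$puncta$row + 1L, g$puncta$col + 1L)])
  expect_gte(hits / nrow(g$puncta), 0.8)
  # nucleus (dim, large) is excluded too
  nuc_frac <- sum(ex & g$nuclei_mask) / sum(g$nuclei_mask)
  expect_gt(nuc_frac, 0.5)
  ex2 <- detect_exclusions(frame + 250, roi_mask)
  # puncta part is offset-invariant; the dim-region part necessarily moves
  # with the offset, so compare only within the bright-blob detections
  expect_identical(ex2 & !g$nuclei_mask, ex & !g$nuclei_mask)
  # frame with no puncta or nuclei: empty exclusion mask
  flat <- matrix(100 + rnorm(96 * 96, 0, 0.1), 96)
  expect_equal(sum(detect_exclusions(flat, roi_mask)), 0)
})

test_that("masks stay disjoint and track truth within 5% across the time course", {
  fix <- small_sim()
  sim <- fix$sim; geom <- fix$geom
  rois <- synthetic_rois(geom, n = 3, seed = 6)
  track <- estimate_drift(sim$stack, channel = "dye")
  stab <- apply_drift(sim$stack, track, mode = "integer")
  work <- apply_drift(denoise(sim$stack, gain = 2, read_sigma = 2), track,
                      mode = "integer")
  masks <- segment_stack(work, rois, method = "mean", mask_channel = "dye")
  tr <- sim$truth$cells
  for (t in c(1, 10, 20, 30, 40)) {
    for (ri in seq_along(rois)) {
      mk <- masks$masks[[t]][[ri]]
      expect_false(any(mk$pm & mk$cyto))
      expect_true(all(which(mk$pm) %in% which(mk$roi)))
    }
  }
  # dye-channel means vs the pixel-weighted ground truth of the ROI: the
  # truth reference is the noiseless, undrifted render restricted to the
  # true membrane band / cytosol region inside the ROI
  s <- pm_index_series(stab, masks, rois[[1]], "dye",
                       background_method = "percentile", background_stack = work)
  clean <- render_stack(geom, fix$model, channels = "dye", n_frames = 40,
                        frame_interval = 60,
                        noise = list(gain = 0, read_sigma = 0),
                        drift = list(step_sigma = 0), seed = 12)
  rm <- rasterize_roi(rois[[1]], c(128, 128))
  band <- geom$membrane_mask & rm
  cyto <- rm & !geom$membrane_mask & !geom$nuclei_mask &
    geom$cell_label_image > 0
  tru_pm <- vapply(1:40, function(t) mean(clean$stack$data[t, 1, , ][band]),
                   numeric(1))
  tru_cy <- vapply(1:40, function(t) mean(clean$stack$data[t, 1, , ][cyto]),
                   numeric(1))
  expect_lt(median(abs(s$pm_mean - tru_pm) / tru_pm), 0.05)
  expect_lt(median(abs(s$cyto_mean - tru_cy) / tru_cy), 0.05)
})
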