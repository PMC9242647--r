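# Geometry generation and stack rendering: determinism, boundary
# properties, mass conservation, ground-truth identities.

test_that("single_cell mode produces one labeled region with a closed membrane band", {
  g <- generate_geometry(1, c(128, 128), "single_cell", seed = 7)
  expect_equal(max(g$cell_label_image), 1)
  expect_gt(sum(g$cell_label_image == 1), 200)
  expect_true(any(g$membrane_mask))
  # the membrane band encloses the interior: every interior pixel path to
  # the border crosses it, i.e. interior and background are disconnected
  # once the band is removed
  inside <- g$cell_label_image == 1 & !g$membrane_mask
  lab <- pmindex:::label_components(inside | g$cell_label_image == 0)
  edge_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  interior_ids <- unique(lab[inside])
  expect_false(any(interior_ids %in% edge_ids))
})

test_that("tissue mode tiles the field and membrane pixels sit on junctions or the edge", {
  g <- generate_geometry(16, c(256, 256), "tissue", seed = 1)
  lab <- g$cell_label_image
  expect_equal(sort(unique(as.vector(lab))), 1:16)
  expect_true(all(lab > 0))
  # every membrane pixel lies within w_mem of a boundary between two labels
  # or of the image edge
  boundary <- pmindex:::boundary_pixels(lab, include_background = TRUE)
  near_boundary <- pmindex:::dilate_disk(boundary, g$w_mem)
  expect_true(all(near_boundary[g$membrane_mask]))
  expect_false(any(g$membrane_mask & g$nuclei_mask))
})

test_that("geometry and rendering are deterministic in the seed", {
  g1 <- generate_geometry(9, c(96, 96), "tissue", seed = 5)
  g2 <- generate_geometry(9, c(96, 96), "tissue", seed = 5)
  expect_identical(g1$cell_label_image, g2$cell_label_image)
  expect_identical(g1$puncta, g2$puncta)
  g3 <- generate_geometry(9, c(96, 96), "tissue", seed = 6)
  expect_false(identical(g1$cell_label_image, g3$cell_label_image))

  m <- small_model()
  r1 <- render_stack(g1, m, channels = c("PIP2", "dye"), n_frames = 5, seed = 3)
  r2 <- render_stack(g1, m, channels = c("PIP2", "dye"), n_frames = 5, seed = 3)
  expect_identical(r1$stack$data, r2$stack$data)
})

test_that("impossible packings raise explicit errors", {
  expect_error(generate_geometry(100, c(32, 32), "tissue", seed = 1), "pack")
  expect_error(generate_geometry(64, c(64, 64), "single_cell", seed = 1), "pack")
})

test_that("degenerate noise and zero drift reproduce the ground-truth render", {
  g <- generate_geometry(4, c(96, 96), "tissue", seed = 2)
  m <- small_model()
  r <- render_stack(g, m, channels = c("PIP2", "dye"), n_frames = 4,
                    noise = list(gain = 0, read_sigma = 0),
                    drift = list(step_sigma = 0), seed = 1)
  # rebuild frame 2 of PIP2 from the ground-truth table
  tr <- r$truth$cells
  img <- r$stack$data[2, 1, , ]
  for (cell in 1:4) {
    row <- tr[tr$frame == 2 & tr$cell == cell & tr$channel == "PIP2", ]
    cyto_clean <- g$cell_label_image == cell & !g$nuclei_mask &
      !g$membrane_mask & !pmindex:::puncta_masks(g)
    expect_equal(mean(img[g$membrane_mask & g$cell_label_image == cell]),
                 row$true_pm_mean, tolerance = 1e-9)
    expect_equal(mean(img[cyto_clean]), row$true_cyto_mean, tolerance = 1e-9)
    # ground-truth identity: index = (pm - bg) / (cyto - bg)
    expect_equal(row$true_pm_index,
                 (row$true_pm_mean - row$true_background) /
                   (row$true_cyto_mean - row$true_background),
                 tolerance = 1e-12)
  }
})

test_that("noiseless per-cell sensor mass is conserved across frames", {
  g <- generate_geometry(6, c(96, 96), "tissue", seed = 4)
  m <- small_model()
  r <- render_stack(g, m, channels = c("PIP2", "PI4P", "Lgl", "dye"),
                    n_frames = 25, noise = list(gain = 0, read_sigma = 0),
                    drift = list(step_sigma = 0), seed = 1, background = 0)
  for (ci in 1:4) {
    for (cell in c(1, 4)) {
      tot <- vapply(1:25, function(t)
        sum(r$stack$data[t, ci, , ][g$cell_label_image == cell]), numeric(1))
      expect_lt(diff(range(tot)) / mean(tot), 0.001)
    }
  }
})

test_that("ATP channel renders cytosolic intensity proportional to occupancy", {
  g <- generate_geometry(4, c(96, 96), "tissue", seed = 2)
  m <- small_model()
  r <- render_stack(g, m, channels = c("ATP"), n_frames = 30,
                    noise = list(gain = 0, read_sigma = 0),
                    drift = list(step_sigma = 0), seed = 1, background = 10)
  tr <- r$truth$cells
  occ <- tr$occupancy[tr$cell == 1]
  cyto <- tr$true_cyto_mean[tr$cell == 1]
  expect_equal(cyto, 10 + 100 * occ, tolerance = 1e-9)
  expect_lt(min(occ), 0.35)  # inhibition drops toward the floor
})

test_that("true PIP2 index reaches half-depletion before PI4P", {
  sim <- small_sim()
  tr <- sim$sim$truth$cells
  half_t <- function(ch) {
    idx <- vapply(sort(unique(tr$frame)), function(t)
      mean(tr$true_pm_index[tr$frame == t & tr$channel == ch]), numeric(1))
    base <- mean(idx[1:3]); flo <- min(idx)
    which(idx < (base + flo) / 2)[1]
  }
  expect_lt(half_t("PIP2"), half_t("PI4P"))
})

test_that("render validates inputs", {
  g <- generate_geometry(2, c(64, 96), "tissue", seed = 1)
  m <- small_model()
  expect_error(render_stack(g, m, channels = "XYZ", n_frames = 3), "XYZ")
  expect_error(render_stack(g, m, channels = "PIP2", n_frames = 1), "n_frames")
  expect_error(render_stack(g, m, channels = "PIP2", n_frames = 3,
                            amplitudes = c(PIP2 = -1)), "amplitudes")
  expect_error(render_stack(g, m, channels = "PIP2", n_frames = 3,
                            noise = list(gain = NA, read_sigma = 0)), "noise")
})

test_that("ground truth writes as plain-text sidecars", {
  g <- generate_geometry(2, c(64, 96), "tissue", seed = 1)
  r <- render_stack(g, small_model(), channels = "PIP2", n_frames = 3,
                    seed = 5)
  dir <- withr::local_tempdir()
  write_ground_truth(r$truth, dir, seed = 5)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  side <- jsonlite::fromJSON(file.path(dir, "simulation.json"))
  expect_equal(side$seed, 5)
  expect_equal(side$t_hypoxia, 300)
  tab <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(tab), 3 * 2)
})
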