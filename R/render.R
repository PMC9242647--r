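#' Render a synthetic time-lapse stack with ground truth
#'
#' Each frame distributes a conserved amount of sensor per cell between the
#' plasma membrane, intracellular puncta and the cytosol according to the
#' kinetic model: the membrane and puncta carry excess signal on top of the
#' cytosolic level (membrane pixels overlay cytoplasm, so a fully cytosolic
#' sensor gives a PM index of 1, not 0), nuclei exclude the sensor, and a
#' constant background offset is added everywhere. The intensimetric `ATP`
#' channel is the exception: it is rendered as purely cytosolic intensity
#' proportional to its occupancy, so its total is deliberately not conserved
#' (its brightness, not its location, reports the signal). Whole-frame
#' random-walk drift, Poisson shot noise (variance `gain * intensity`) and
#' additive Gaussian read noise are applied after the noiseless render;
#' ground truth is computed from the noiseless, undrifted render.
#'
#' @param geometry a [generate_geometry()] result.
#' @param model a [kinetic_model()]; every requested channel must be one of
#'   its sensors.
#' @param channels channels to render (names into `model$sensors`).
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds per frame.
#' @param amplitudes named per-channel mean cell brightness above background
#'   (arbitrary units, all > 0).
#' @param noise list with `gain` (Poisson scaling, 0 disables shot noise)
#'   and `read_sigma` (Gaussian read noise SD, 0 disables).
#' @param drift list with `step_sigma`: per-frame random-walk step SD in
#'   pixels (0 disables drift).
#' @param seed integer seed; identical seeds give bit-identical stacks.
#' @param background constant background offset added to every pixel.
#' @param pm_fraction named per-channel baseline fraction of the sensor pool
#'   on the membrane (ATP-like channels use 0).
#' @return list with `stack` (an [image_stack()]) and `truth` (a
#'   `GroundTruth` list: per frame/cell/channel table, drift track, model,
#'   geometry).
#' @export
render_stack <- function(geometry, model, channels = c("PI4P", "PIP2", "dye"),
                         n_frames = 90L, frame_interval = 60,
                         amplitudes = NULL, noise = list(gain = 2, read_sigma = 2),
                         drift = list(step_sigma = 0.5), seed = 1L,
                         background = 10,
                         pm_fraction = c(PI4P = 0.35, PIP2 = 0.4, Lgl = 0.4,
                                         ATP = 0, dye = 0.5)) {
  if (n_frames < 2L) stop("n_frames must be >= 2")
  missing_ch <- setdiff(channels, names(model$sensors))
  if (length(missing_ch))
    stop(sprintf("channels not in model: %s", paste(missing_ch, collapse = ", ")))
  if (is.null(amplitudes))
    amplitudes <- stats::setNames(rep(100, length(channels)), channels)
  if (any(amplitudes[channels] <= 0) || any(!is.finite(amplitudes[channels])))
    stop("amplitudes must be positive and finite")
  gain <- noise$gain %||% 0; read_sigma <- noise$read_sigma %||% 0
  if (!is.finite(gain) || !is.finite(read_sigma) || gain < 0 || read_sigma < 0)
    stop("noise parameters must be finite and >= 0")
  step_sigma <- drift$step_sigma %||% 0

  lab <- geometry$cell_label_image
  h <- nrow(lab); w <- ncol(lab)
  n_cells <- max(lab)
  mem <- geometry$membrane_mask
  nuc <- geometry$nuclei_mask
  puncta_mask_cell <- puncta_masks(geometry)

  # per-cell pixel index sets
  cells <- lapply(seq_len(n_cells), function(id) {
    cell <- lab == id
    list(cell = which(cell),
         cyto_region = which(cell & !nuc),          # sensor-accessible area
         mem = which(cell & mem),
         punc = which(cell & puncta_mask_cell),
         cyto_clean = which(cell & !nuc & !mem & !puncta_mask_cell))
  })

  times <- (seq_len(n_frames) - 1) * frame_interval
  with_seed(seed, {
    steps_y <- c(0, stats::rnorm(n_frames - 1L, 0, step_sigma))
    steps_x <- c(0, stats::rnorm(n_frames - 1L, 0, step_sigma))
    dy <- cumsum(steps_y); dx <- cumsum(steps_x)

    data <- array(0, dim = c(n_frames, length(channels), h, w))
    truth_rows <- vector("list", n_frames * length(channels) * n_cells)
    ti <- 1L
    for (t in seq_len(n_frames)) {
      for (ci in seq_along(channels)) {
        ch <- channels[ci]
        amp <- amplitudes[[ch]]
        p0 <- if (ch %in% names(pm_fraction)) pm_fraction[[ch]] else 0.4
        q0 <- model$sensors[[ch]]$puncta_fraction
        f <- simulate_occupancy(model, ch, times[t])
        g <- if (q0 > 0) simulate_occupancy(model, ch, times[t], pool = "puncta") else 0
        img <- matrix(background, h, w)
        for (id in seq_len(n_cells)) {
          cx <- cells[[id]]
          M <- amp * length(cx$cell)
          if (ch == "ATP") {
            cyto_dens <- amp * f
            img[cx$cyto_region] <- img[cx$cyto_region] + cyto_dens
            truth_rows[[ti]] <- data.frame(
              frame = t, time_s = times[t], cell = id, channel = ch,
              occupancy = f, puncta_occupancy = NA_real_,
              true_pm_mean = NA_real_, true_cyto_mean = background + cyto_dens,
              true_background = background, true_pm_index = NA_real_)
          } else {
            pm_mass <- p0 * f * M
            punc_mass <- if (length(cx$punc)) q0 * g * M else 0
            cyto_mass <- M - pm_mass - punc_mass
            cyto_dens <- cyto_mass / length(cx$cyto_region)
            pm_dens <- if (length(cx$mem)) pm_mass / length(cx$mem) else 0
            punc_dens <- if (length(cx$punc)) punc_mass / length(cx$punc) else 0
            img[cx$cyto_region] <- img[cx$cyto_region] + cyto_dens
            img[cx$mem] <- img[cx$mem] + pm_dens
            img[cx$punc] <- img[cx$punc] + punc_dens
            truth_rows[[ti]] <- data.frame(
              frame = t, time_s = times[t], cell = id, channel = ch,
              occupancy = f, puncta_occupancy = if (q0 > 0) g else NA_real_,
              true_pm_mean = background + cyto_dens + pm_dens,
              true_cyto_mean = background + cyto_dens,
              true_background = background,
              true_pm_index = 1 + pm_dens / cyto_dens)
          }
          ti <- ti + 1L
        }
        data[t, ci, , ] <- img
      }
    }
    # drift, then noise (noise is per detected photon, after motion)
    for (t in seq_len(n_frames)) {
      for (ci in seq_along(channels)) {
        img <- data[t, ci, , ]
        if (step_sigma > 0 && (dy[t] != 0 || dx[t] != 0))
          img <- shift_image(img, dy[t], dx[t], fill = background)
        if (gain > 0)
          img <- matrix(stats::rpois(h * w, pmax(img, 0) / gain) * gain, h, w)
        if (read_sigma > 0)
          img <- img + matrix(stats::rnorm(h * w, 0, read_sigma), h, w)
        data[t, ci, , ] <- img
      }
    }
    truth <- structure(list(
      cells = do.call(rbind, truth_rows),
      drift = data.frame(frame = seq_len(n_frames), dy = dy, dx = dx),
      model = model, geometry = geometry, background = background,
      amplitudes = amplitudes, pm_fraction = pm_fraction),
      class = "GroundTruth")
    stack <- image_stack(data, channels = channels, pixel_size = geometry$pixel_size,
                         frame_interval = frame_interval,
                         meta = list(seed = seed))
    list(stack = stack, truth = truth)
  })
}

# Logical mask of all puncta disks in a geometry.
puncta_masks <- function(geometry) {
  lab <- geometry$cell_label_image
  h <- nrow(lab); w <- ncol(lab)
  out <- matrix(FALSE, h, w)
  p <- geometry$puncta
  if (nrow(p) == 0) return(out)
  gr <- matrix(seq_len(h), h, w); gc <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (k in seq_len(nrow(p))) {
    out <- out | ((gr - (p$row[k] + 1L))^2 + (gc - (p$col[k] + 1L))^2 <=
                    p$radius[k]^2)
  }
  out & !geometry$membrane_mask & !geometry$nuclei_mask
}

#' Write the ground truth beside a stack
#'
#' Writes the per-frame/cell/channel truth table as CSV and the kinetic
#' model, drift track and seed as a JSON sidecar, mirroring the on-disk
#' layout of a `simulate` CLI run.
#'
#' @param truth a `GroundTruth` from [render_stack()].
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$cells, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$drift, file.path(dir, "drift_truth.csv"),
                   row.names = FALSE)
  model <- truth$model
  jsonlite::write_json(
    list(seed = seed, t_hypoxia = model$t_hypoxia, t_reoxy = model$t_reoxy,
         sensors = lapply(model$sensors, unclass),
         background = truth$background,
         amplitudes = as.list(truth$amplitudes),
         pm_fraction = as.list(truth$pm_fraction)),
    file.path(dir, "simulation.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
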