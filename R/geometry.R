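#' Generate synthetic cell geometry
#'
#' `tissue` mode emulates a polygonal epithelium: seed points on a jittered
#' grid define a discrete Voronoi tessellation that tiles the whole field,
#' so every boundary pixel touches two cell labels or the image edge.
#' `single_cell` mode emulates isolated cultured cells: non-touching blobby
#' polygons on a dark background. Each cell gets a membrane band of width
#' `w_mem` pixels along its boundary, a nuclear disk kept clear of the
#' membrane, and candidate puncta positions in its cytoplasm.
#'
#' @param n_cells number of cells (>= 1).
#' @param image_shape `c(height, width)` in pixels.
#' @param mode `"tissue"` or `"single_cell"`.
#' @param seed integer seed; identical seeds give identical geometry.
#' @param w_mem membrane band width in pixels.
#' @param pixel_size micrometres per pixel (metadata only).
#' @param n_puncta number of candidate puncta per cell.
#' @param puncta_radius radius (px) of rendered puncta disks (2-4 px is the
#'   intended scale).
#' @return a `TissueGeometry` list: `cell_label_image` (integer matrix,
#'   0 = background), `membrane_mask`, `nuclei_mask` (logical matrices),
#'   `puncta` (data frame cell/row/col/radius), `mode`, `w_mem`,
#'   `pixel_size`.
#' @export
generate_geometry <- function(n_cells, image_shape, mode = c("tissue", "single_cell"),
                              seed = 1L, w_mem = 3L, pixel_size = 0.2,
                              n_puncta = 4L, puncta_radius = 3) {
  mode <- match.arg(mode)
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  if (n_cells < 1L) stop("n_cells must be >= 1")
  with_seed(seed, {
    if (mode == "tissue") {
      if (h * w / n_cells < 200)
        stop(sprintf("cannot pack %d cells of >= 200 px^2 into %d x %d",
                     n_cells, h, w))
      lab <- tissue_labels(n_cells, h, w)
    } else {
      lab <- single_cell_labels(n_cells, h, w)
    }
    boundary <- boundary_pixels(lab, include_background = TRUE)
    membrane <- dilate_disk(boundary, (w_mem - 1) / 2)
    if (mode == "single_cell") membrane <- membrane & lab > 0
    nuclei <- matrix(FALSE, h, w)
    puncta <- list()
    clearance <- dilate_disk(membrane, 2)
    for (id in seq_len(max(lab))) {
      cell <- lab == id
      interior <- cell & !clearance
      if (!any(interior)) next
      idx <- which(interior, arr.ind = TRUE)
      cen <- round(colMeans(idx))
      r_nuc <- max(2, round(sqrt(sum(cell) / pi) * 0.4))
      # pull the nucleus center to the nearest interior pixel
      d2 <- (idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2
      cen <- idx[which.min(d2), ]
      gr <- matrix(seq_len(h), h, w); gc <- matrix(seq_len(w), h, w, byrow = TRUE)
      disk <- (gr - cen[1])^2 + (gc - cen[2])^2 <= r_nuc^2
      nuclei <- nuclei | (disk & interior)
      # puncta candidates in cytosol (outside nucleus and membrane clearance)
      cyto <- interior & !nuclei
      free <- which(cyto, arr.ind = TRUE)
      keep <- free[(free[, 1] - cen[1])^2 + (free[, 2] - cen[2])^2 >
                     (r_nuc + puncta_radius)^2, , drop = FALSE]
      if (nrow(keep) > 0 && n_puncta > 0) {
        pick <- keep[sample.int(nrow(keep), min(n_puncta, nrow(keep))), ,
                     drop = FALSE]
        puncta[[length(puncta) + 1L]] <-
          data.frame(cell = id, row = pick[, 1] - 1L, col = pick[, 2] - 1L,
                     radius = puncta_radius)
      }
    }
    puncta <- if (length(puncta)) do.call(rbind, puncta) else
      data.frame(cell = integer(), row = integer(), col = integer(),
                 radius = numeric())
    structure(list(cell_label_image = lab, membrane_mask = membrane,
                   nuclei_mask = nuclei & !membrane, puncta = puncta,
                   mode = mode, w_mem = w_mem, pixel_size = pixel_size),
              class = "TissueGeometry")
  })
}

# Discrete Voronoi tessellation from jittered-grid seeds; exactly n labels.
tissue_labels <- function(n_cells, h, w) {
  gr <- max(1L, round(sqrt(n_cells * h / w)))
  gc <- ceiling(n_cells / gr)
  while (gr * gc < n_cells) gc <- gc + 1L
  sy <- h / gr; sx <- w / gc
  centers <- expand.grid(i = seq_len(gr), j = seq_len(gc))
  centers <- centers[seq_len(n_cells), , drop = FALSE]
  cy <- (centers$i - 0.5) * sy + stats::runif(n_cells, -0.3 * sy, 0.3 * sy)
  cx <- (centers$j - 0.5) * sx + stats::runif(n_cells, -0.3 * sx, 0.3 * sx)
  py <- matrix(seq_len(h), h, w); px <- matrix(seq_len(w), h, w, byrow = TRUE)
  best_d <- matrix(Inf, h, w); lab <- matrix(0L, h, w)
  for (k in seq_len(n_cells)) {
    d <- (py - cy[k])^2 + (px - cx[k])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]; lab[upd] <- k
  }
  lab
}

# Non-touching blobby cells on background (label 0).
single_cell_labels <- function(n_cells, h, w) {
  gr <- max(1L, round(sqrt(n_cells * h / w)))
  gc <- ceiling(n_cells / gr)
  while (gr * gc < n_cells) gc <- gc + 1L
  sy <- h / gr; sx <- w / gc
  rad <- 0.30 * min(sy, sx)
  if (pi * (0.7 * rad)^2 < 200)
    stop(sprintf("cannot pack %d non-touching cells of >= 200 px^2 into %d x %d",
                 n_cells, h, w))
  lab <- matrix(0L, h, w)
  py <- matrix(seq_len(h), h, w); px <- matrix(seq_len(w), h, w, byrow = TRUE)
  slots <- expand.grid(i = seq_len(gr), j = seq_len(gc))[seq_len(n_cells), ]
  for (k in seq_len(n_cells)) {
    cy <- (slots$i[k] - 0.5) * sy + stats::runif(1, -0.1 * sy, 0.1 * sy)
    cx <- (slots$j[k] - 0.5) * sx + stats::runif(1, -0.1 * sx, 0.1 * sx)
    # radial perturbation with low-frequency lobes makes the outline blobby
    ph <- stats::runif(2, 0, 2 * pi); amp <- stats::runif(2, 0.05, 0.15)
    th <- atan2(py - cy, px - cx)
    rr <- rad * (1 + amp[1] * sin(2 * th + ph[1]) + amp[2] * sin(3 * th + ph[2]))
    inside <- (py - cy)^2 + (px - cx)^2 <= rr^2
    lab[inside & lab == 0L] <- k
  }
  lab
}

# Pixels adjacent (4-connectivity) to a different label, the image edge, or
# (optionally not) the background.
boundary_pixels <- function(lab, include_background = TRUE) {
  h <- nrow(lab); w <- ncol(lab)
  pad <- matrix(-1L, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- lab
  ctr <- pad[2:(h + 1), 2:(w + 1)]
  out <- matrix(FALSE, h, w)
  for (d in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    nb <- pad[2:(h + 1) + d[1], 2:(w + 1) + d[2]]
    diff <- nb != ctr
    if (!include_background) diff <- diff & nb > 0L
    out <- out | diff
  }
  out & ctr > 0L
}

#' Generate junction ROIs from a synthetic geometry
#'
#' Mimics the drawing protocol: square ROIs centered on cell-cell junctions
#' (tissue mode), or cell-region ROIs covering part of one cell including PM
#' and cytoplasm (single-cell mode). Junctions touching the image edge are
#' avoided.
#'
#' @param geometry a [generate_geometry()] result.
#' @param n number of ROIs requested (at most one per cell pair / cell).
#' @param size_px ROI side length in pixels (default ~27 um^2 at 0.2 um/px).
#' @param seed RNG seed for the junction choice.
#' @return list of [roi_spec()] objects; the attribute `cells` maps each ROI
#'   to the cell ids it touches.
#' @export
synthetic_rois <- function(geometry, n = 8L, size_px = 26L, seed = 1L) {
  lab <- geometry$cell_label_image
  h <- nrow(lab); w <- ncol(lab)
  half <- size_px / 2
  with_seed(seed, {
    rois <- list(); cells <- list()
    if (geometry$mode == "tissue") {
      # candidate junction pixels: horizontally/vertically adjacent label pairs
      right <- lab[, -w] != lab[, -1] & lab[, -w] > 0 & lab[, -1] > 0
      down <- lab[-h, ] != lab[-1, ] & lab[-h, ] > 0 & lab[-1, ] > 0
      cand <- rbind(
        cbind(which(right, arr.ind = TRUE),
              a = lab[, -w][right], b = lab[, -1][right]),
        cbind(which(down, arr.ind = TRUE),
              a = lab[-h, ][down], b = lab[-1, ][down]))
      ok <- cand[, 1] > half + 2 & cand[, 1] < h - half - 2 &
        cand[, 2] > half + 2 & cand[, 2] < w - half - 2
      cand <- cand[ok, , drop = FALSE]
      pair_id <- paste(pmin(cand[, 3], cand[, 4]), pmax(cand[, 3], cand[, 4]))
      pairs <- split(seq_len(nrow(cand)), pair_id)
      take <- sample(length(pairs), min(n, length(pairs)))
      for (k in take) {
        rows <- pairs[[k]]
        # center of the shared junction segment
        ctr <- round(colMeans(cand[rows, 1:2, drop = FALSE]))
        # snap to the nearest actual junction pixel
        d2 <- (cand[rows, 1] - ctr[1])^2 + (cand[rows, 2] - ctr[2])^2
        ctr <- cand[rows[which.min(d2)], 1:2]
        r0 <- ctr[1] - 1 - half; c0 <- ctr[2] - 1 - half  # 0-based
        rois[[length(rois) + 1L]] <- roi_spec(
          sprintf("junction_%s", gsub(" ", "_", names(pairs)[k])),
          rbind(c(r0, c0), c(r0, c0 + size_px), c(r0 + size_px, c0 + size_px),
                c(r0 + size_px, c0)),
          kind = "junction")
        cells[[length(cells) + 1L]] <- unique(as.vector(cand[rows, 3:4]))
      }
    } else {
      for (id in seq_len(min(n, max(lab)))) {
        px <- which(lab == id, arr.ind = TRUE)
        ctr <- colMeans(px)
        ext <- max(px[, 1]) - min(px[, 1])
        # cover part of the cell: from inside the cytoplasm out past the PM
        r0 <- max(0, min(px[, 1]) - 3 - 1); r1 <- min(h - 1, ctr[1] + ext / 4)
        c0 <- max(0, min(px[, 2]) - 3 - 1); c1 <- min(w - 1, max(px[, 2]) + 3 - 1)
        rois[[length(rois) + 1L]] <- roi_spec(
          sprintf("cell_%d", id),
          rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0)),
          kind = "cell_region")
        cells[[length(cells) + 1L]] <- id
      }
    }
    if (!length(rois)) stop("no usable junctions found for ROI placement")
    attr(rois, "cells") <- cells
    rois
  })
}
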