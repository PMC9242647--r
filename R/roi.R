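#' Polygonal region of interest
#'
#' An `RoiSpec` is a labeled simple polygon in pixel coordinates, the unit of
#' quantification. Coordinates are 0-based `(row, col)` pairs at pixel
#' centers, row 0 at the top, matching the on-disk JSON schema. A polygon
#' covers the pixels whose centers fall inside it (even-odd rule, half-open
#' so that shoelace area and pixel count agree for axis-aligned rectangles).
#'
#' @param label text label used in output tables and error messages.
#' @param vertices n x 2 numeric matrix (or list of `[r, c]` pairs) of
#'   polygon vertices in 0-based pixel coordinates; at least 3 vertices,
#'   non-self-intersecting.
#' @param kind `"junction"` for a region spanning a cell-cell junction
#'   (tissue protocol) or `"cell_region"` for a patch covering PM plus
#'   cytoplasm of one cell (cultured-cell protocol).
#' @param target_area_um2 optional area guidance in square micrometres;
#'   [check_roi_area()] warns (never errors) when the polygon is outside it.
#' @return An object of class `RoiSpec`.
#' @export
roi_spec <- function(label, vertices, kind = c("junction", "cell_region"),
                     target_area_um2 = NULL) {
  kind <- match.arg(kind)
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop(sprintf("ROI '%s': polygon needs >= 3 (row, col) vertices", label))
  if (any(!is.finite(vertices)))
    stop(sprintf("ROI '%s': non-finite vertex coordinates", label))
  if (!polygon_is_simple(vertices))
    stop(sprintf("ROI '%s': polygon is self-intersecting", label))
  area <- polygon_area(vertices)
  if (area <= 0)
    stop(sprintf("ROI '%s': polygon has zero area", label))
  structure(list(label = as.character(label), vertices = vertices,
                 kind = kind, target_area_um2 = target_area_um2),
            class = "RoiSpec")
}

#' @export
print.RoiSpec <- function(x, ...) {
  cat(sprintf("RoiSpec '%s' (%s): %d vertices, area %.1f px^2\n",
              x$label, x$kind, nrow(x$vertices), polygon_area(x$vertices)))
  invisible(x)
}

# Shoelace area of an (r, c) polygon.
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 2] * v[j, 1] - v[j, 2] * v[, 1])) / 2
}

# Proper-intersection test for two segments (shared endpoints allowed).
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k <= i) next
      # skip adjacent edges (share a vertex)
      if (abs(i - k) <= 1L || (i == 1L && k == n)) next
      i2 <- if (i == n) 1L else i + 1L
      k2 <- if (k == n) 1L else k + 1L
      if (segments_cross(v[i, ], v[i2, ], v[k, ], v[k2, ])) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' @param roi an [roi_spec()].
#' @param image_shape `c(height, width)` of the target image in pixels.
#' @return logical `height x width` matrix; `TRUE` for pixels whose center
#'   lies inside the polygon.
#' @export
rasterize_roi <- function(roi, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  v <- roi$vertices
  if (any(v[, 1] < -0.5 | v[, 1] > h - 0.5 | v[, 2] < -0.5 | v[, 2] > w - 0.5))
    stop(sprintf("ROI '%s': vertices outside image bounds (%d x %d)",
                 roi$label, h, w))
  r0 <- max(0L, floor(min(v[, 1]))); r1 <- min(h - 1L, ceiling(max(v[, 1])))
  c0 <- max(0L, floor(min(v[, 2]))); c1 <- min(w - 1L, ceiling(max(v[, 2])))
  rows <- r0:r1; cols <- c0:c1
  # crossing-number test, vectorized over the bbox; a tiny nudge keeps pixel
  # centers off polygon edges so the parity is well defined
  eps <- 1e-9
  ridx <- rep(rows, times = length(cols))
  cidx <- rep(cols, each = length(rows))
  py <- ridx + eps
  px <- cidx + eps
  inside <- rep(FALSE, length(py))
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 1]; xi <- v[i, 2]; yj <- v[j, 1]; xj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mask <- matrix(FALSE, h, w)
  mask[cbind(ridx + 1L, cidx + 1L)[inside, , drop = FALSE]] <- TRUE
  if (!any(mask)) stop(sprintf("ROI '%s': rasterizes to an empty mask", roi$label))
  mask
}

#' Warn when an ROI is outside its target area guidance
#'
#' Mirrors the drawing guidance for junction ROIs (tissue protocol uses
#' regions of roughly 20-40 um^2); the guidance is advisory only.
#'
#' @param roi an [roi_spec()].
#' @param pixel_size micrometres per pixel.
#' @return the ROI area in um^2, invisibly.
#' @export
check_roi_area <- function(roi, pixel_size) {
  area_um2 <- polygon_area(roi$vertices) * pixel_size^2
  tgt <- roi$target_area_um2 %||% if (roi$kind == "junction") c(20, 40) else NULL
  if (!is.null(tgt) && (area_um2 < min(tgt) || area_um2 > max(tgt)))
    warning(sprintf("ROI '%s': area %.1f um^2 outside guidance [%g, %g] um^2",
                    roi$label, area_um2, min(tgt), max(tgt)))
  invisible(area_um2)
}
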