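# PM / cytosol mask generation and background detection. Two mask routes
# mirror the two imaging protocols: ROI mean-thresholding (tissue junctions)
# and a trous wavelet detail thresholding (cultured cells / dye channel).

#' PM mask by ROI mean-thresholding
#'
#' The PM mask is the set of ROI pixels at or above the mean pixel value of
#' the ROI (ties included, so together with [cytosol_mask()] the ROI is
#' exhaustively partitioned before exclusions). Degenerate constant ROIs
#' select the whole ROI and raise a warning.
#'
#' @param frame numeric matrix.
#' @param roi an [roi_spec()] or a logical ROI mask.
#' @return logical mask with attribute `threshold` (the ROI mean).
#' @export
mean_threshold_pm_mask <- function(frame, roi) {
  roi_mask <- as_roi_mask(roi, dim(frame))
  thr <- mean(frame[roi_mask])
  if (!is.finite(thr)) stop("ROI mean is not finite")
  mask <- roi_mask & frame >= thr
  if (all(mask[roi_mask]))
    warning("constant ROI: PM mask equals the entire ROI")
  attr(mask, "threshold") <- thr
  mask
}

#' Cytosol mask complementary to a PM mask
#'
#' ROI pixels strictly below the ROI-mean threshold, minus exclusions and
#' minus a `guard_px`-pixel dilation ring of the PM mask (a guard band
#' against PSF bleed-through from the membrane).
#'
#' @param frame numeric matrix.
#' @param roi an [roi_spec()] or logical ROI mask.
#' @param pm_mask logical PM mask (must lie within the ROI).
#' @param exclusions optional logical mask of pixels to drop (nuclei,
#'   puncta, saturated regions).
#' @param guard_px guard ring width in pixels (default 1).
#' @return logical mask with attribute `threshold`.
#' @export
cytosol_mask <- function(frame, roi, pm_mask, exclusions = NULL, guard_px = 1L) {
  roi_mask <- as_roi_mask(roi, dim(frame))
  if (any(pm_mask & !roi_mask)) stop("pm_mask extends outside the ROI")
  thr <- mean(frame[roi_mask])
  if (!is.finite(thr)) stop("ROI mean is not finite")
  mask <- roi_mask & frame < thr
  mask <- mask & !dilate_disk(pm_mask, guard_px)
  if (!is.null(exclusions)) mask <- mask & !exclusions
  if (!any(mask))
    stop("cytosol mask is empty; enlarge the ROI so it contains cytoplasm")
  attr(mask, "threshold") <- thr
  mask
}

#' PM mask from à trous wavelet details
#'
#' Sums the selected detail planes and keeps pixels above `k_sigma` times a
#' robust noise scale (the median absolute deviation of the level-1 detail,
#' scaled to sigma), then removes components smaller than `min_area` pixels
#' and intersects with the ROI. Because detail planes ignore additive
#' offsets, the mask is invariant to constant intensity shifts.
#'
#' @param frame numeric matrix (use the membrane-dye channel when one
#'   exists: a translocating sensor cannot define the PM once it has left it).
#' @param roi an [roi_spec()] or logical ROI mask.
#' @param levels_used detail levels summed into the feature image.
#' @param k_sigma threshold in robust sigma units.
#' @param min_area minimum connected-component area in pixels.
#' @param rel_thresh secondary threshold as a fraction of the ROI's peak
#'   detail sum (default 0.5 = full width at half maximum). Mid-scale
#'   detail planes of a sharp band carry a positive halo several pixels
#'   wide; against a noise-only threshold the halo passes and the mask
#'   balloons, so pixels must also reach half the ridge peak. Set 0 to
#'   disable.
#' @return logical mask with attributes `threshold` and `sigma`.
#' @export
wavelet_pm_mask <- function(frame, roi, levels_used = c(2L, 3L), k_sigma = 3,
                            min_area = 10L, rel_thresh = 0.5) {
  roi_mask <- as_roi_mask(roi, dim(frame))
  dec <- atrous_decompose(frame, levels = max(levels_used))
  D <- Reduce(`+`, dec$details[levels_used])
  if (all(D == 0)) stop("wavelet detail sum is identically zero")
  sigma <- stats::mad(dec$details[[1]])
  thr <- max(k_sigma * sigma, rel_thresh * max(D[roi_mask]))
  mask <- D >= thr & D > 0
  mask <- remove_small_components(mask, min_area)
  mask <- mask & roi_mask
  attr(mask, "threshold") <- thr
  attr(mask, "sigma") <- sigma
  mask
}

#' Detect the image background level
#'
#' The protocol rule is the minimal pixel value of the whole image
#' (`method = "min"`, the default); a low percentile is offered as a
#' noise-robust alternative.
#'
#' @param frame numeric matrix.
#' @param method `"min"` or `"percentile"`.
#' @param p percentile in percent (for `method = "percentile"`).
#' @return scalar background intensity.
#' @export
detect_background <- function(frame, method = c("min", "percentile"), p = 0.1) {
  method <- match.arg(method)
  if (length(frame) == 0) stop("empty frame")
  if (method == "min") min(frame)
  else unname(stats::quantile(frame, p / 100, names = FALSE))
}

#' Detect exclusion regions (puncta and nuclei) inside an ROI
#'
#' Automated proxy for the manual avoidance of nuclei and intracellular
#' puncta: the union of (a) bright small blobs, level-1+2 wavelet details
#' above `k_sigma` robust sigmas forming components of at most
#' `puncta_max_area` pixels, and (b) large dim regions below half the ROI
#' median exceeding `nucleus_min_area` pixels. May be empty.
#'
#' @param frame numeric matrix.
#' @param roi an [roi_spec()] or logical ROI mask.
#' @param k_sigma puncta detection threshold in sigma units.
#' @param puncta_min_area,puncta_max_area component area range counted as a
#'   punctum (the lower bound rejects single-pixel noise excursions; the
#'   upper bound must accommodate the full wavelet footprint of a bright
#'   punctum — a 3 px-radius disk plus its detail halo spans ~100 px —
#'   while staying below any membrane-band component).
#' @param nucleus_min_area minimum component area counted as a nucleus
#'   (default 50 px, ~2 um^2 at 0.2 um/px: small enough to catch a nucleus
#'   corner intruding into a junction ROI, large enough that smoothed noise
#'   dips never form qualifying components).
#' @return logical exclusion mask (subset of the ROI).
#' @export
detect_exclusions <- function(frame, roi, k_sigma = 3, puncta_min_area = 4L,
                              puncta_max_area = 200L,
                              nucleus_min_area = 50L) {
  roi_mask <- as_roi_mask(roi, dim(frame))
  dec <- atrous_decompose(frame, levels = 2L)
  D <- dec$details[[1]] + dec$details[[2]]
  sigma <- stats::mad(dec$details[[1]])
  # components are detected and sized frame-wide (so a nucleus whose corner
  # intrudes into the ROI still qualifies by its full area), then the final
  # mask is restricted to the ROI
  bright <- D >= k_sigma * sigma & D > 0
  puncta <- matrix(FALSE, nrow(frame), ncol(frame))
  if (any(bright)) {
    lab <- label_components(bright)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= puncta_min_area & sizes <= puncta_max_area)
    puncta <- lab > 0 & lab %in% keep
  }
  med <- stats::median(frame[roi_mask])
  dim_mask <- frame < 0.5 * med
  nuclei <- matrix(FALSE, nrow(frame), ncol(frame))
  if (any(dim_mask)) {
    lab <- label_components(dim_mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= nucleus_min_area)
    nuclei <- lab > 0 & lab %in% keep
  }
  (puncta | nuclei) & roi_mask
}

# Pixels carrying significant fine-scale (level 1+2) detail: puncta,
# membrane, any sharp structure. Used to purge the cytosol mask.
bright_detail_mask <- function(frame, k_sigma = 3) {
  dec <- atrous_decompose(frame, levels = 2L)
  D <- dec$details[[1]] + dec$details[[2]]
  sigma <- stats::mad(dec$details[[1]])
  D >= k_sigma * sigma & D > 0
}

# Accept either an RoiSpec (rasterized on demand) or a logical mask.
as_roi_mask <- function(roi, image_dim) {
  if (inherits(roi, "RoiSpec")) return(rasterize_roi(roi, image_dim))
  if (is.logical(roi)) {
    if (!all(dim(roi) == image_dim)) stop("ROI mask dimensions do not match frame")
    if (!any(roi)) stop("ROI mask is empty")
    return(roi)
  }
  stop("roi must be an RoiSpec or a logical mask")
}

#' Build per-frame PM/cytosol masks for a set of ROIs
#'
#' Orchestrates the per-frame mask computation across a stack. Masks are
#' driven by `mask_channel` (a membrane dye when available; a translocating
#' sensor channel cannot define the PM once the signal has left it — if the
#' masking channel's PM mask collapses on some frame the previous valid mask
#' is reused and the frame is flagged). Exclusions (puncta, nuclei) are
#' detected per measured channel and united.
#'
#' @param stack an [image_stack()] (typically the denoised working copy).
#' @param rois list of [roi_spec()] (or a single one).
#' @param method `"mean"` or `"atrous"`.
#' @param mask_channel channel driving the masks.
#' @param exclude_channels channels scanned for puncta/nuclei exclusions
#'   (default: the mask channel only).
#' @param guard_px guard ring width between PM and cytosol masks.
#' @param k_sigma,levels_used,min_area wavelet parameters (atrous method).
#' @return a `MaskSet`: list with `masks[[frame]][[roi]]` entries holding
#'   `pm`, `cyto`, `exclusion` logical masks, the `threshold` used, and a
#'   `fallback` flag; plus `provenance` metadata.
#' @export
segment_stack <- function(stack, rois, method = c("mean", "atrous"),
                          mask_channel = 1L, exclude_channels = NULL,
                          guard_px = 1L, k_sigma = 3, levels_used = c(2L, 3L),
                          min_area = 10L) {
  method <- match.arg(method)
  if (inherits(rois, "RoiSpec")) rois <- list(rois)
  nf <- n_frames(stack)
  shape <- dim(stack$data)[3:4]
  roi_masks <- lapply(rois, rasterize_roi, image_shape = shape)
  exclude_channels <- exclude_channels %||% mask_channel
  # wavelet operations run on a padded bounding box around each ROI, not the
  # full frame: identical masks, order-of-magnitude faster
  pad <- max(2^max(levels_used) * 4 + 2, 24)
  boxes <- lapply(roi_masks, function(rm) {
    idx <- which(rm, arr.ind = TRUE)
    list(r = max(1L, min(idx[, 1]) - pad):min(shape[1], max(idx[, 1]) + pad),
         c = max(1L, min(idx[, 2]) - pad):min(shape[2], max(idx[, 2]) + pad))
  })
  masks <- vector("list", nf)
  last_valid <- vector("list", length(rois))
  for (t in seq_len(nf)) {
    frame <- get_frame(stack, t, mask_channel)
    per_roi <- vector("list", length(rois))
    for (ri in seq_along(rois)) {
      rm <- roi_masks[[ri]]
      bx <- boxes[[ri]]
      rm_c <- rm[bx$r, bx$c]
      frame_c <- frame[bx$r, bx$c]
      paste_full <- function(m) {
        full <- matrix(FALSE, shape[1], shape[2])
        if (!is.null(m)) full[bx$r, bx$c] <- m
        full
      }
      excl_c <- matrix(FALSE, length(bx$r), length(bx$c))
      struct_c <- excl_c
      for (ch in exclude_channels) {
        exf <- get_frame(stack, t, ch)[bx$r, bx$c]
        excl_c <- excl_c | detect_exclusions(exf, rm_c, k_sigma = k_sigma)
        # bright fine-scale structure in a measured channel is never cytosol,
        # whatever its component size (a punctum whose wavelet component
        # merges with the membrane band escapes the size-filtered rule)
        struct_c <- struct_c | bright_detail_mask(exf, k_sigma = k_sigma)
      }
      pm_c <- tryCatch({
        if (method == "mean") mean_threshold_pm_mask(frame_c, rm_c)
        else wavelet_pm_mask(frame_c, rm_c, levels_used = levels_used,
                             k_sigma = k_sigma, min_area = min_area)
      }, warning = function(w) NULL, error = function(e) NULL)
      fallback <- FALSE
      if (is.null(pm_c) || !any(pm_c)) {
        pm_c <- last_valid[[ri]]
        fallback <- TRUE
        if (is.null(pm_c))
          stop(sprintf("ROI '%s': no valid PM mask on frame %d and no earlier mask to fall back on",
                       rois[[ri]]$label, t))
      } else {
        last_valid[[ri]] <- pm_c
      }
      cyto_c <- tryCatch(
        cytosol_mask(frame_c, rm_c, pm_c, exclusions = excl_c | struct_c,
                     guard_px = guard_px),
        error = function(e) NULL)
      per_roi[[ri]] <- list(pm = paste_full(pm_c & !excl_c),
                            cyto = if (is.null(cyto_c)) NULL else paste_full(cyto_c),
                            exclusion = paste_full(excl_c), roi = rm,
                            threshold = attr(pm_c, "threshold"),
                            fallback = fallback)
    }
    masks[[t]] <- per_roi
  }
  structure(list(masks = masks,
                 rois = rois,
                 provenance = list(method = method, mask_channel = mask_channel,
                                   guard_px = guard_px, k_sigma = k_sigma,
                                   levels_used = levels_used,
                                   min_area = min_area)),
            class = "MaskSet")
}
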