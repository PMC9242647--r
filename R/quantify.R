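# The central statistics: PM localization index, normalized PM index, and
# normalized cytosolic intensity for intensimetric sensors.

PM_INDEX_EPS <- 1e-6

#' PM localization index
#'
#' The background-corrected ratio of mean PM to mean cytosol intensity:
#' `(pm_mean - background) / (cyto_mean - background)`. A value of 1 means
#' no PM enrichment (fully cytosolic sensor).
#'
#' @param pm_mean mean intensity over the PM mask.
#' @param cyto_mean mean intensity over the cytosol mask.
#' @param background background intensity.
#' @return dimensionless ratio. In this scalar form a near-zero denominator
#'   (below `1e-6` of the dynamic range) is an error; in series context the
#'   frame is flagged invalid instead.
#' @export
pm_index <- function(pm_mean, cyto_mean, background) {
  den <- cyto_mean - background
  if (any(!is.finite(den)) || any(den <= PM_INDEX_EPS * max(abs(cyto_mean), 1)))
    stop("cytosol mean does not exceed background; PM index undefined")
  (pm_mean - background) / den
}

#' Per-frame PM index series for one ROI and channel
#'
#' Measures per-frame means over the PM and cytosol masks (exclusions
#' removed), the per-frame background, and the PM index. Saturated pixels
#' (at or above the stack's bit-depth maximum) are excluded from the means
#' and reported as a per-frame saturated fraction; frames with no usable
#' pixels or a non-positive denominator are flagged invalid rather than
#' poisoning the series with NaNs.
#'
#' @param stack an [image_stack()] to measure (raw or denoised copy,
#'   per the `measure_on` policy).
#' @param masks a `MaskSet` from [segment_stack()].
#' @param roi the [roi_spec()] (or its index in `masks`).
#' @param channel channel to measure.
#' @param background_method,background_p see [detect_background()].
#' @param background_stack optional stack on which the per-frame background
#'   is detected (the denoised working copy, where the minimum-pixel rule is
#'   far less noise-biased); defaults to `stack` itself.
#' @param pm_core_px erosion (px) applied to the PM mask for the PM mean
#'   only: the PM-side counterpart of the cytosol guard ring. Rim pixels of
#'   the mask are partial-volume mixtures of membrane and cytosol (PSF,
#'   residual subpixel motion), so including them biases the PM mean low;
#'   the default of 1 measures the mask core. Set 0 for strict
#'   whole-mask-mean protocol fidelity. Ignored (with a fallback to the full
#'   mask) whenever erosion would empty the mask.
#' @return a `pm_index_series` data frame: `frame, time_s, pm_mean,
#'   cyto_mean, background, pm_index, n_pm_px, n_cyto_px, sat_frac, valid`,
#'   with attributes `roi` and `channel`.
#' @export
pm_index_series <- function(stack, masks, roi, channel,
                            background_method = "min", background_p = 0.1,
                            background_stack = NULL, pm_core_px = 1L) {
  background_stack <- background_stack %||% stack
  ri <- resolve_roi_index(masks, roi)
  nf <- n_frames(stack)
  if (length(masks$masks) != nf)
    stop(sprintf("MaskSet covers %d frames but stack has %d",
                 length(masks$masks), nf))
  sat <- saturation_level(stack)
  times <- frame_times(stack)
  out <- data.frame(frame = seq_len(nf), time_s = times, pm_mean = NA_real_,
                    cyto_mean = NA_real_, background = NA_real_,
                    pm_index = NA_real_, n_pm_px = 0L, n_cyto_px = 0L,
                    sat_frac = 0, valid = FALSE)
  for (t in seq_len(nf)) {
    m <- masks$masks[[t]][[ri]]
    img <- get_frame(stack, t, channel)
    bg <- detect_background(get_frame(background_stack, t, channel),
                            method = background_method, p = background_p)
    out$background[t] <- bg
    ok <- img < sat
    pm_meas <- if (pm_core_px > 0) {
      core <- erode_disk(m$pm, pm_core_px)
      if (any(core)) core else m$pm
    } else m$pm
    pm_px <- pm_meas & ok
    n_roi_pm <- sum(pm_meas)
    out$sat_frac[t] <- if (n_roi_pm > 0) 1 - sum(pm_px) / n_roi_pm else 0
    if (is.null(m$cyto)) next
    cy_px <- m$cyto & ok
    out$n_pm_px[t] <- sum(pm_px)
    out$n_cyto_px[t] <- sum(cy_px)
    if (out$n_pm_px[t] == 0L || out$n_cyto_px[t] == 0L) next
    pm_mean <- mean(img[pm_px]); cyto_mean <- mean(img[cy_px])
    out$pm_mean[t] <- pm_mean; out$cyto_mean[t] <- cyto_mean
    den <- cyto_mean - bg
    if (is.finite(den) && den > PM_INDEX_EPS * max(abs(cyto_mean), 1)) {
      out$pm_index[t] <- (pm_mean - bg) / den
      out$valid[t] <- TRUE
    }
  }
  if (!any(out$valid)) stop("no valid frames in PM index series")
  label <- if (inherits(roi, "RoiSpec")) roi$label else masks$rois[[ri]]$label
  structure(out, roi = label, channel = as.character(channel),
            class = c("pm_index_series", "data.frame"))
}

resolve_roi_index <- function(masks, roi) {
  if (is.numeric(roi)) return(as.integer(roi))
  if (inherits(roi, "RoiSpec")) {
    labels <- vapply(masks$rois, `[[`, "", "label")
    ri <- match(roi$label, labels)
    if (is.na(ri)) stop(sprintf("ROI '%s' not present in MaskSet", roi$label))
    return(ri)
  }
  stop("roi must be an RoiSpec or an index")
}

#' Normalize a PM index series to its baseline
#'
#' Default convention `index_minus_one` rescales the PM enrichment above 1:
#' `N(t) = (PMI(t) - 1) / mean(PMI - 1 over the baseline frames)`, so the
#' baseline maps to 1 and a fully cytosolic sensor (PMI = 1) maps to 0.
#' `plain` divides the index itself by its baseline mean. The baseline is
#' the mean over the first `baseline_n` valid frames (so a "0 min only"
#' baseline is `baseline_n = 1`). Normalizing an already-normalized series
#' returns it unchanged.
#'
#' @param series a [pm_index_series()].
#' @param baseline_n number of leading valid frames in the baseline.
#' @param convention `"index_minus_one"` or `"plain"`.
#' @return the series with a `norm_pm_index` column and normalization
#'   metadata attributes.
#' @export
normalize_series <- function(series, baseline_n = 3L,
                             convention = c("index_minus_one", "plain")) {
  convention <- match.arg(convention)
  if (!is.null(attr(series, "normalization"))) return(series)
  if (baseline_n < 1L) stop("baseline_n must be >= 1")
  valid_idx <- which(series$valid)
  if (length(valid_idx) < baseline_n)
    stop(sprintf("ROI '%s': only %d valid frames for a %d-frame baseline",
                 attr(series, "roi"), length(valid_idx), baseline_n))
  base_idx <- valid_idx[seq_len(baseline_n)]
  if (convention == "index_minus_one") {
    base <- mean(series$pm_index[base_idx] - 1)
    if (!is.finite(base) || base <= PM_INDEX_EPS)
      stop(sprintf(
        "ROI '%s': baseline PM index is ~1 (no PM enrichment at start); cannot normalize",
        attr(series, "roi")))
    series$norm_pm_index <- (series$pm_index - 1) / base
  } else {
    base <- mean(series$pm_index[base_idx])
    if (!is.finite(base) || abs(base) <= PM_INDEX_EPS)
      stop(sprintf("ROI '%s': baseline PM index is ~0; cannot normalize",
                   attr(series, "roi")))
    series$norm_pm_index <- series$pm_index / base
  }
  series$norm_pm_index[!series$valid] <- NA_real_
  attr(series, "normalization") <- list(convention = convention,
                                        baseline_frames = base_idx,
                                        baseline_value = base)
  series
}

#' Normalized cytosolic intensity series (intensimetric sensors)
#'
#' For purely cytosolic reporters (e.g. an intensimetric ATP sensor) whose
#' brightness, not localization, is the signal: the background-subtracted
#' mean over the cytosol mask (or the whole ROI minus exclusions when no
#' cytosol mask is usable), divided by its mean over the first `baseline_n`
#' valid frames.
#'
#' @param stack an [image_stack()].
#' @param masks a `MaskSet`.
#' @param roi the [roi_spec()] or index.
#' @param channel channel to measure.
#' @param baseline_n baseline frame count.
#' @param background_method,background_p see [detect_background()].
#' @return data frame `frame, time_s, cyto_mean, background, cyto_index,
#'   valid` with attributes `roi`, `channel`.
#' @export
cyto_intensity_series <- function(stack, masks, roi, channel, baseline_n = 3L,
                                  background_method = "min", background_p = 0.1) {
  ri <- resolve_roi_index(masks, roi)
  nf <- n_frames(stack)
  sat <- saturation_level(stack)
  out <- data.frame(frame = seq_len(nf), time_s = frame_times(stack),
                    cyto_mean = NA_real_, background = NA_real_,
                    cyto_index = NA_real_, valid = FALSE)
  for (t in seq_len(nf)) {
    m <- masks$masks[[t]][[ri]]
    img <- get_frame(stack, t, channel)
    bg <- detect_background(img, method = background_method, p = background_p)
    out$background[t] <- bg
    px <- if (!is.null(m$cyto)) m$cyto else (m$roi & !m$exclusion)
    px <- px & img < sat
    if (!any(px)) next
    out$cyto_mean[t] <- mean(img[px])
    out$valid[t] <- TRUE
  }
  valid_idx <- which(out$valid)
  if (length(valid_idx) < baseline_n)
    stop("not enough valid frames for the baseline")
  base_idx <- valid_idx[seq_len(baseline_n)]
  base <- mean(out$cyto_mean[base_idx] - out$background[base_idx])
  if (!is.finite(base) || base <= PM_INDEX_EPS)
    stop("baseline cytosolic intensity does not exceed background")
  out$cyto_index <- (out$cyto_mean - out$background) / base
  out$cyto_index[!out$valid] <- NA_real_
  label <- if (inherits(roi, "RoiSpec")) roi$label else masks$rois[[ri]]$label
  structure(out, roi = label, channel = as.character(channel),
            normalization = list(baseline_frames = base_idx, baseline_value = base),
            class = c("cyto_index_series", "data.frame"))
}
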