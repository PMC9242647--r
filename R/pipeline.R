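#' One-call quantification pipeline
#'
#' Orchestrates the full chain on a multi-channel movie: drift estimation on
#' the mask channel, lossless integer stabilization, Poisson-Gaussian
#' denoising into a working copy (masks and background only), per-frame
#' PM/cytosol segmentation driven by the mask channel, and background-
#' corrected, baseline-normalized PM-index series for every requested
#' channel. Intensities are measured on raw (stabilized) pixels by default;
#' the denoised copy only decides where and what the background is — the
#' combination found to track simulated ground truth within a few percent.
#'
#' @param stack an [image_stack()].
#' @param rois list of [roi_spec()].
#' @param channels channels to quantify (default: all but the mask channel).
#' @param mask_channel channel driving masks and registration (a membrane
#'   dye when present).
#' @param mask_method `"mean"` or `"atrous"`.
#' @param gain,read_sigma noise-model parameters for denoising.
#' @param denoise_strength detail threshold (sigma units); 0 disables.
#' @param register estimate and undo stage drift first?
#' @param drift_mode `"integer"` (default, lossless) or `"subpixel"`.
#' @param upsample drift estimation refinement factor.
#' @param background_method,background_p background rule, applied to the
#'   denoised working copy (robust low percentile by default).
#' @param measure_on `"raw"` (default) or `"denoised"`.
#' @param baseline_n,normalization see [normalize_series()].
#' @param exclude_channels channels scanned for puncta/nuclei exclusions
#'   (default: the measured channels).
#' @param guard_px,pm_core_px mask guard ring and PM-core erosion.
#' @return list with `series` (list of normalized [pm_index_series()], one
#'   per ROI x channel), `masks`, `track` (or NULL), `work` (the denoised,
#'   stabilized working copy), `raw` (the stabilized measurement stack).
#' @export
quantify_stack <- function(stack, rois, channels = NULL, mask_channel = "dye",
                           mask_method = "mean", gain = 2, read_sigma = 2,
                           denoise_strength = 3, register = TRUE,
                           drift_mode = "integer", upsample = 10L,
                           background_method = "percentile", background_p = 0.1,
                           measure_on = c("raw", "denoised"), baseline_n = 3L,
                           normalization = "index_minus_one",
                           exclude_channels = NULL, guard_px = 1L,
                           pm_core_px = 1L) {
  measure_on <- match.arg(measure_on)
  if (inherits(rois, "RoiSpec")) rois <- list(rois)
  channels <- channels %||% setdiff(stack$channels, mask_channel)
  exclude_channels <- exclude_channels %||% channels
  track <- NULL
  raw <- stack
  dn <- if (denoise_strength > 0)
    denoise(stack, gain = gain, read_sigma = read_sigma,
            strength = denoise_strength) else stack
  if (register) {
    track <- estimate_drift(stack, channel = mask_channel, upsample = upsample)
    raw <- apply_drift(stack, track, mode = drift_mode)
    work <- apply_drift(dn, track, mode = drift_mode)
  } else {
    work <- dn
  }
  masks <- segment_stack(work, rois, method = mask_method,
                         mask_channel = mask_channel,
                         exclude_channels = exclude_channels,
                         guard_px = guard_px)
  meas <- if (measure_on == "raw") raw else work
  series <- list()
  for (roi in rois) {
    for (ch in channels) {
      s <- pm_index_series(meas, masks, roi, ch,
                           background_method = background_method,
                           background_p = background_p,
                           background_stack = work, pm_core_px = pm_core_px)
      s <- normalize_series(s, baseline_n = baseline_n,
                            convention = normalization)
      series[[paste(attr(s, "roi"), ch, sep = ":")]] <- s
    }
  }
  list(series = series, masks = masks, track = track, work = work, raw = raw)
}
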