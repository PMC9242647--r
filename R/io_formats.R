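# ROI JSON, results-table CSV, run configuration and provenance records.

#' Read ROIs from a JSON file
#'
#' The schema is a JSON array of objects
#' `{"label": ..., "kind": "junction"|"cell_region", "vertices": [[r, c], ...]}`
#' with 0-based pixel coordinates. Malformed polygons (fewer than 3 vertices,
#' self-intersections, zero area) are rejected with an error naming the ROI.
#'
#' @param path JSON file path.
#' @return list of [roi_spec()] objects.
#' @export
read_rois <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!is.list(raw)) stop("ROI file must contain a JSON array of ROI objects")
  lapply(raw, function(r) {
    if (is.null(r$label) || is.null(r$vertices))
      stop("ROI entry missing 'label' or 'vertices'")
    roi_spec(r$label, r$vertices, kind = r$kind %||% "junction",
             target_area_um2 = r$target_area_um2)
  })
}

#' Write ROIs to a JSON file
#' @param rois list of [roi_spec()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  if (inherits(rois, "RoiSpec")) rois <- list(rois)
  out <- lapply(rois, function(r) {
    x <- list(label = r$label, kind = r$kind,
              vertices = apply(unname(r$vertices), 1, as.numeric,
                               simplify = FALSE))
    if (!is.null(r$target_area_um2)) x$target_area_um2 <- r$target_area_um2
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write PM-index series to a results CSV
#'
#' Concatenates one or more series (see [pm_index_series()]) into the
#' canonical long-format table with columns `movie_id, roi, channel, frame,
#' time_s, pm_mean, cyto_mean, background, pm_index, norm_pm_index, n_pm_px,
#' n_cyto_px, sat_frac, valid`. Values round-trip through [read_table()] to
#' better than 1e-9.
#'
#' @param series a series data frame or list of them.
#' @param path output CSV path.
#' @param movie_id identifier recorded in the first column.
#' @return `path`, invisibly.
#' @export
write_table <- function(series, path, movie_id = "movie") {
  if (is.data.frame(series)) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(movie_id = movie_id,
               roi = attr(s, "roi") %||% NA_character_,
               channel = attr(s, "channel") %||% NA_character_,
               frame = s$frame, time_s = s$time_s,
               pm_mean = s$pm_mean, cyto_mean = s$cyto_mean,
               background = s$background, pm_index = s$pm_index,
               norm_pm_index = s$norm_pm_index %||% rep(NA_real_, nrow(s)),
               n_pm_px = s$n_pm_px, n_cyto_px = s$n_cyto_px,
               sat_frac = s$sat_frac, valid = s$valid,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_table()]
#' @param path CSV path.
#' @return data frame in the canonical long format.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run configuration
#'
#' Bundles the knobs shared across pipeline stages with their defaults. The
#' defaults mirror the quantification protocol: mean-threshold masks for
#' tissue, background from the whole-frame minimum, baseline over the first
#' 3 frames, normalization of (PM index - 1).
#'
#' @param pixel_size micrometres per pixel (> 0).
#' @param frame_interval seconds between frames (> 0).
#' @param channels named character vector mapping sensor roles to channel
#'   names, e.g. `c(mask = "dye")`.
#' @param mask_method `"mean"` (ROI mean-threshold) or `"atrous"` (B3-spline
#'   wavelet).
#' @param background_method `"min"` or `"percentile"`.
#' @param background_p percentile (percent) for `background_method =
#'   "percentile"`.
#' @param baseline_n number of leading frames averaged into the baseline.
#' @param normalization `"index_minus_one"` or `"plain"`.
#' @param measure_on `"denoised"` or `"raw"`: intensities measured on the
#'   denoised working copy (default) or on raw values.
#' @param guard_px width of the guard ring separating PM and cytosol masks.
#' @param k_sigma,levels_used,min_area wavelet-mask parameters.
#' @param seed integer seed recorded for provenance.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(pixel_size = 0.2, frame_interval = 60,
                       channels = c(mask = "dye"), mask_method = "mean",
                       background_method = "min", background_p = 0.1,
                       baseline_n = 3L, normalization = "index_minus_one",
                       measure_on = "denoised", guard_px = 1L,
                       k_sigma = 3, levels_used = c(2L, 3L), min_area = 10L,
                       seed = 1L) {
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("pixel_size and frame_interval must be > 0")
  stopifnot(mask_method %in% c("mean", "atrous"),
            background_method %in% c("min", "percentile"),
            normalization %in% c("index_minus_one", "plain"),
            measure_on %in% c("denoised", "raw"),
            baseline_n >= 1L)
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 channels = channels, mask_method = mask_method,
                 background_method = background_method,
                 background_p = background_p, baseline_n = as.integer(baseline_n),
                 normalization = normalization, measure_on = measure_on,
                 guard_px = as.integer(guard_px), k_sigma = k_sigma,
                 levels_used = as.integer(levels_used),
                 min_area = as.integer(min_area), seed = as.integer(seed)),
            class = "run_config")
}

# Check that every channel the config references exists in the stack.
validate_config <- function(config, stack) {
  missing <- setdiff(unname(config$channels), stack$channels)
  if (length(missing))
    stop(sprintf("config references channels absent from the stack: %s",
                 paste(missing, collapse = ", ")))
  invisible(TRUE)
}

#' Write a machine-readable provenance record
#'
#' Every CLI run drops one of these beside its outputs: package version,
#' seed, and the full configuration.
#'
#' @param path output JSON path.
#' @param config a [run_config()] or arbitrary named list.
#' @param seed the seed the run used.
#' @param extra optional named list merged into the record.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed, extra = list()) {
  rec <- c(list(package = "pmindex",
                version = tryCatch(as.character(utils::packageVersion("pmindex")),
                                   error = function(e) "dev"),
                seed = seed, config = unclass(config)), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration JSON
#'
#' Reads a JSON file with any subset of [run_config()]'s fields and returns
#' a complete validated config (unspecified fields take the defaults).
#'
#' @param path JSON file path.
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, raw)
}

#' Converter stub for proprietary ROI formats
#'
#' Reading ImageJ `.roi`/`RoiSet.zip` (or other proprietary ROI containers)
#' is deliberately out of scope: export ROIs as polygons and convert them to
#' the JSON schema of [read_rois()] (`{label, kind, vertices: [[r, c], ...]}`,
#' 0-based pixel coordinates) upstream. This stub exists so the boundary is
#' explicit and discoverable.
#'
#' @param path path to the unsupported file.
#' @return never returns; always errors with conversion instructions.
#' @export
convert_roi_file <- function(path) {
  stop(sprintf(paste0(
    "reading '%s' is not supported: proprietary ROI formats are out of scope. ",
    "Export the polygons and convert to the JSON schema of read_rois() ",
    "({label, kind, vertices: [[row, col], ...]}, 0-based pixel coordinates)."),
    path))
}
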