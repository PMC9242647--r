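#' Figure-style time-course panel
#'
#' Plots one or more PM-index (or cytosolic-index) series against time with
#' event markers at stress onset and reoxygenation, either as per-cell
#' traces or as a mean +/- SD (or SEM) band per channel. Time axis labels
#' use h:min:s. Input tables are never mutated.
#'
#' @param panel a list describing the panel: `series` (list of series data
#'   frames), `value` (column to plot, default `"norm_pm_index"`),
#'   `events` (numeric times in s, e.g. `c(hypoxia = 600, reoxy = 3600)`),
#'   `aggregate` (`"traces"` or `"band"`), `band_stat` (`"sd"` or `"sem"`),
#'   `ylab`, `main`.
#' @param out_path output PNG path.
#' @param width,height,res PNG device geometry.
#' @return `out_path`, invisibly.
#' @export
plot_series <- function(panel, out_path, width = 900, height = 600, res = 120) {
  series <- panel$series
  if (is.null(series) || length(series) == 0)
    stop("panel selection is empty: no series to plot")
  value <- panel$value %||% "norm_pm_index"
  aggregate <- panel$aggregate %||% "traces"
  band_stat <- panel$band_stat %||% "sd"
  channels <- vapply(series, function(s) attr(s, "channel") %||% "series", "")
  cols <- grDevices::hcl.colors(max(3, length(unique(channels))), "Dark 3")
  names(cols)[seq_along(unique(channels))] <- unique(channels)
  times <- series[[1]]$time_s
  if (!all(vapply(series, function(s) identical(s$time_s, times), TRUE)))
    stop("selected series do not share a time base")

  grDevices::png(out_path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  vals <- lapply(series, function(s) s[[value]])
  ylim <- range(unlist(vals), na.rm = TRUE)
  plot(NA, xlim = range(times), ylim = ylim, xlab = "time (h:min:s)",
       ylab = panel$ylab %||% value, main = panel$main %||% "", axes = FALSE)
  at <- pretty(times)
  graphics::axis(1, at = at, labels = format_hms(at))
  graphics::axis(2); graphics::box()
  for (ev in panel$events %||% numeric(0))
    graphics::abline(v = ev, lty = 2, col = "grey40")
  if (aggregate == "band") {
    for (ch in unique(channels)) {
      vs <- do.call(cbind, vals[channels == ch])
      m <- rowMeans(vs, na.rm = TRUE)
      s <- apply(vs, 1, stats::sd, na.rm = TRUE)
      if (band_stat == "sem") s <- s / sqrt(rowSums(!is.na(vs)))
      col <- cols[[ch]]
      ok <- is.finite(m) & is.finite(s)
      graphics::polygon(c(times[ok], rev(times[ok])),
                        c((m + s)[ok], rev((m - s)[ok])),
                        col = grDevices::adjustcolor(col, 0.25), border = NA)
      graphics::lines(times[ok], m[ok], col = col, lwd = 2)
    }
  } else {
    for (i in seq_along(series))
      graphics::lines(times, vals[[i]], col = cols[[channels[i]]])
  }
  graphics::legend("topright", legend = unique(channels),
                   col = cols[unique(channels)], lwd = 2, bty = "n")
  invisible(out_path)
}

# Seconds -> "h:mm:ss" labels echoing the time-stamp convention of the
# source movies.
format_hms <- function(s) {
  s <- round(s)
  sprintf("%d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}
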