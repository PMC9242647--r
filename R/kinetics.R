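# Summarize normalized PM-index time series into depletion/recovery
# parameters and compare half-transition times between sensors.

# Piecewise-exponential trajectory used both to fit series and to reason
# about them: baseline B until t_hyp + delay, exponential decay to floor F,
# then from t_reoxy + rec_delay exponential rise to plateau P. Continuous by
# construction (no overshoot term: fits are deliberately simpler than the
# generator, which may add a transient pulse).
kinetics_curve <- function(par, t, t_hyp, t_reoxy) {
  B <- par[1]; delay <- par[2]; r_dep <- par[3]; F <- par[4]
  rec_delay <- par[5]; r_rec <- par[6]; P <- par[7]
  t_on <- t_hyp + delay
  t_ron <- max(t_reoxy + rec_delay, t_on)  # recovery cannot precede onset
  v <- rep.int(B, length(t))
  dec <- t >= t_on & t < t_ron
  if (any(dec)) v[dec] <- F + (B - F) * exp(-r_dep * (t[dec] - t_on))
  v_ron <- F + (B - F) * exp(-r_dep * (t_ron - t_on))
  rec <- t >= t_ron
  if (any(rec)) v[rec] <- P + (v_ron - P) * exp(-r_rec * (t[rec] - t_ron))
  v
}

# Analytic gradient of the sum of squared residuals of kinetics_curve.
# The curve is differentiable in the parameters at almost every t (the
# breakpoint set has measure zero on the sampling grid), so L-BFGS-B can
# use the exact gradient instead of 2p finite-difference evaluations.
kinetics_sse_grad <- function(par, t, values, t_hyp, t_reoxy) {
  B <- par[1]; delay <- par[2]; r_dep <- par[3]; F <- par[4]
  rec_delay <- par[5]; r_rec <- par[6]; P <- par[7]
  t_on <- t_hyp + delay
  t_ron <- max(t_reoxy + rec_delay, t_on)
  n <- length(t)
  J <- matrix(0, n, 7)
  v <- rep.int(B, n)
  base <- t < t_on
  J[base, 1] <- 1
  dec <- t >= t_on & t < t_ron
  if (any(dec)) {
    E <- exp(-r_dep * (t[dec] - t_on))
    v[dec] <- F + (B - F) * E
    J[dec, 1] <- E
    J[dec, 2] <- (B - F) * r_dep * E
    J[dec, 3] <- -(B - F) * (t[dec] - t_on) * E
    J[dec, 4] <- 1 - E
  }
  E_ron <- exp(-r_dep * (t_ron - t_on))
  v_ron <- F + (B - F) * E_ron
  rec <- t >= t_ron
  if (any(rec)) {
    R <- exp(-r_rec * (t[rec] - t_ron))
    v[rec] <- P + (v_ron - P) * R
    # dv_ron/d(theta) chain through the decay branch evaluated at t_ron
    J[rec, 1] <- E_ron * R
    J[rec, 2] <- (B - F) * r_dep * E_ron * R
    J[rec, 3] <- -(B - F) * (t_ron - t_on) * E_ron * R
    J[rec, 4] <- (1 - E_ron) * R
    # t_ron moves with rec_delay: v_ron changes and so does the R clock
    dv_ron_dtron <- -r_dep * (B - F) * E_ron
    J[rec, 5] <- dv_ron_dtron * R + (v_ron - P) * r_rec * R
    J[rec, 6] <- -(v_ron - P) * (t[rec] - t_ron) * R
    J[rec, 7] <- 1 - R
  }
  resid <- values - v
  as.vector(-2 * crossprod(J, resid))
}

#' Fit depletion/recovery kinetics to a normalized PM-index series
#'
#' Bounded least squares of a continuous piecewise-exponential model
#' (baseline, delayed exponential depletion to a floor, delayed exponential
#' recovery to a plateau) with three deterministic multi-starts from a
#' coarse rate grid seeded by raw half-crossings. Half-transition times are
#' computed from the fitted parameters: `t50_dep` is where the fitted curve
#' crosses halfway between baseline and floor, `t50_rec` halfway between the
#' value at recovery onset and the plateau (the underlying figures report
#' orderings without defining a t50; this definition is this package's).
#'
#' @param time frame times in seconds.
#' @param values normalized PM index per frame (NAs allowed and dropped).
#' @param t_hypoxia stress onset (s).
#' @param t_reoxy reoxygenation (s).
#' @return a `kinetics_fit` list: `par` (named: baseline, delay,
#'   depletion_rate, floor, recovery_delay, recovery_rate, plateau),
#'   `t50_dep`, `t50_rec` (absolute s, NA when undefined), `rmse`,
#'   `converged`, `flagged` and, when flagged, raw-crossing fallback t50s.
#' @export
fit_kinetics <- function(time, values, t_hypoxia, t_reoxy) {
  keep <- is.finite(time) & is.finite(values)
  time <- time[keep]; values <- values[keep]
  n_pre <- sum(time <= t_hypoxia)
  n_hyp <- sum(time > t_hypoxia & time <= t_reoxy)
  n_rec <- sum(time > t_reoxy)
  if (n_hyp < 5L || n_rec < 5L)
    stop("need >= 5 valid frames in the hypoxia and recovery phases")
  t_end <- max(time)

  B0 <- if (n_pre > 0) mean(values[time <= t_hypoxia]) else values[1]
  # floor estimate: last 3 frames before reoxygenation
  F0 <- mean(values[time <= t_reoxy][order(time[time <= t_reoxy],
                                           decreasing = TRUE)[1:3]])
  P0 <- mean(values[order(time, decreasing = TRUE)[1:3]])

  if (stats::sd(values) < 1e-9 || abs(B0 - F0) < 1e-6) {
    # constant (or never-depleting) series: rate 0, t50 undefined
    par <- c(baseline = B0, delay = 0, depletion_rate = 0, floor = B0,
             recovery_delay = 0, recovery_rate = 0, plateau = B0)
    return(structure(list(par = par, t50_dep = NA_real_, t50_rec = NA_real_,
                          rmse = stats::sd(values), converged = TRUE,
                          flagged = TRUE, reason = "constant series"),
                     class = "kinetics_fit"))
  }

  # raw half-crossings for initialization
  half_dep <- (B0 + F0) / 2
  cross_dep <- time[time > t_hypoxia & values < half_dep]
  t_half_dep0 <- if (length(cross_dep)) min(cross_dep) else (t_hypoxia + t_reoxy) / 2
  half_rec <- (F0 + P0) / 2
  cross_rec <- time[time > t_reoxy & values > half_rec]
  t_half_rec0 <- if (length(cross_rec)) min(cross_rec) else (t_reoxy + t_end) / 2

  obj <- function(par) {
    pred <- kinetics_curve(par, time, t_hypoxia, t_reoxy)
    sum((values - pred)^2)
  }
  grad <- function(par) kinetics_sse_grad(par, time, values, t_hypoxia, t_reoxy)
  lower <- c(-2, 0, 1e-5, -2, 0, 1e-5, -2)
  upper <- c(5, t_reoxy - t_hypoxia, 0.5, 5, t_end - t_reoxy, 0.5, 5)
  clamp <- function(p) pmin(pmax(p, lower), upper)
  parscale <- c(1, 300, 0.003, 0.3, 120, 0.006, 1)
  best <- NULL
  for (r0 in c(0.001, 0.003, 0.01)) {
    start <- clamp(c(B0,
                     max(0, t_half_dep0 - t_hypoxia - log(2) / r0),
                     r0, F0,
                     max(0, t_half_rec0 - t_reoxy - log(2) / (2 * r0)),
                     2 * r0, P0))
    fit <- tryCatch(
      stats::optim(start, obj, grad, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 100, parscale = parscale)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (!is.null(best)) {
    # tight polish from the best coarse optimum
    polish <- tryCatch(
      stats::optim(clamp(best$par), obj, grad, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4,
                                  parscale = parscale)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }
  flagged <- is.null(best) || best$convergence != 0
  if (is.null(best)) {
    # total failure: raw-crossing fallback
    return(structure(list(
      par = stats::setNames(rep(NA_real_, 7),
                            c("baseline", "delay", "depletion_rate", "floor",
                              "recovery_delay", "recovery_rate", "plateau")),
      t50_dep = t_half_dep0, t50_rec = t_half_rec0, rmse = NA_real_,
      converged = FALSE, flagged = TRUE, reason = "optimizer failure"),
      class = "kinetics_fit"))
  }
  par <- stats::setNames(best$par,
                         c("baseline", "delay", "depletion_rate", "floor",
                           "recovery_delay", "recovery_rate", "plateau"))
  B <- par[1]; F <- par[4]; P <- par[7]
  t50_dep <- if (F < B && par["depletion_rate"] > 1e-5)
    unname(t_hypoxia + par["delay"] + log(2) / par["depletion_rate"]) else NA_real_
  t_ron <- t_reoxy + par["recovery_delay"]
  v_ron <- kinetics_curve(par, t_ron, t_hypoxia, t_reoxy)
  t50_rec <- if (P > v_ron && par["recovery_rate"] > 1e-5)
    unname(t_ron + log(2) / par["recovery_rate"]) else NA_real_
  structure(list(par = par, t50_dep = t50_dep, t50_rec = t50_rec,
                 rmse = sqrt(best$value / length(values)),
                 converged = best$convergence == 0, flagged = flagged),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("kinetics_fit:", if (x$flagged) "[flagged]" else "", "\n")
  print(round(x$par, 6))
  cat(sprintf("  t50_dep = %.1f s, t50_rec = %.1f s, rmse = %.4g\n",
              x$t50_dep, x$t50_rec, x$rmse))
  invisible(x)
}

#' Compare half-transition times between two sensors
#'
#' Paired per-cell differences of t50 (`a - b`) for the chosen phase, with
#' the median, a seeded percentile-bootstrap confidence interval over cells
#' (cells, not frames, are the independent replicates), and the fraction of
#' cells in which `a` precedes `b`.
#'
#' @param fits_a,fits_b lists of [fit_kinetics()] results, paired by cell
#'   (same length, same order).
#' @param phase `"depletion"` or `"recovery"`.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed making the CI deterministic.
#' @param conf confidence level.
#' @return an `OrderingResult` list: `phase`, `delta` (per-cell
#'   differences), `median`, `ci` (length 2), `frac_a_first`, `n`.
#' @export
compare_onsets <- function(fits_a, fits_b, phase = c("depletion", "recovery"),
                           n_boot = 1000L, seed = 1L, conf = 0.95) {
  phase <- match.arg(phase)
  if (length(fits_a) != length(fits_b))
    stop("fits_a and fits_b must be paired by cell (equal lengths)")
  pick <- function(f) if (phase == "depletion") f$t50_dep else f$t50_rec
  ta <- vapply(fits_a, pick, numeric(1))
  tb <- vapply(fits_b, pick, numeric(1))
  keep <- is.finite(ta) & is.finite(tb)
  d <- ta[keep] - tb[keep]
  n <- length(d)
  if (n < 5L) stop("need >= 5 paired cells with defined t50")
  med <- stats::median(d)
  ci <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    boot_med <- apply(idx, 1, function(i) stats::median(d[i]))
    stats::quantile(boot_med, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  })
  structure(list(phase = phase, delta = d, median = med, ci = ci,
                 frac_a_first = mean(d < 0), n = n),
            class = "OrderingResult")
}

#' @export
print.OrderingResult <- function(x, ...) {
  cat(sprintf(
    "OrderingResult (%s): median dt50 = %.1f s, %d%% CI [%.1f, %.1f], n = %d, frac(a first) = %.2f\n",
    x$phase, x$median, 95, x$ci[1], x$ci[2], x$n, x$frac_a_first))
  invisible(x)
}

#' Simulate a noisy normalized PM-index series directly
#'
#' Series-level shortcut used for kinetics simulation studies: under the
#' rendering model the noiseless normalized PM index equals the occupancy
#' curve, so a cell's observed series is the occupancy plus i.i.d. Gaussian
#' measurement noise. The default noise SD of 0.05 (5 % of baseline)
#' reflects the frame-to-frame scatter of the image-level pipeline at
#' default SNR.
#'
#' @param model a [kinetic_model()].
#' @param sensor sensor name.
#' @param n_frames,frame_interval sampling grid.
#' @param noise_sd Gaussian SD added to the normalized index.
#' @param seed RNG seed.
#' @return data frame `time_s`, `value`, `truth`.
#' @export
simulate_index_series <- function(model, sensor, n_frames = 90L,
                                  frame_interval = 60, noise_sd = 0.05,
                                  seed = 1L) {
  t <- (seq_len(n_frames) - 1) * frame_interval
  truth <- simulate_occupancy(model, sensor, t)
  obs <- with_seed(seed, truth + stats::rnorm(length(t), 0, noise_sd))
  data.frame(time_s = t, value = obs, truth = truth)
}
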