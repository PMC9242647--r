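#' Per-sensor piecewise depletion/recovery kinetics
#'
#' The occupancy of a sensor is the fraction of its membrane-bound pool that
#' is currently on the plasma membrane, on a 0-1 scale (1 = pre-stress
#' baseline). The model is piecewise exponential: occupancy holds at 1 until
#' `depletion_delay` seconds after stress onset (optionally with a transient
#' overshoot pulse), decays exponentially toward `floor` during the stress,
#' and from `recovery_delay` seconds after reoxygenation rises exponentially
#' from its current value toward `plateau`. The pieces join continuously by
#' construction. An optional intracellular puncta pool follows the same
#' shape with its own delays (puncta empty before the PM pool and refill
#' after it, as seen for the PI4P reporter).
#'
#' @param depletion_delay seconds between stress onset and the start of PM
#'   depletion.
#' @param depletion_rate exponential depletion rate (1/s).
#' @param floor hypoxic occupancy floor, in `[0, plateau]`.
#' @param recovery_delay seconds between reoxygenation and the start of
#'   recovery.
#' @param recovery_rate exponential recovery rate (1/s).
#' @param plateau post-recovery occupancy, in `[floor, 1 + overshoot_amp]`.
#' @param overshoot_amp amplitude of the transient early-hypoxia overshoot
#'   (fraction above baseline; 0 disables it).
#' @param overshoot_decay decay rate of the overshoot pulse (1/s).
#' @param puncta_fraction fraction of the sensor pool held in intracellular
#'   puncta at baseline (0 disables the pool).
#' @param puncta_depletion_delay,puncta_recovery_delay delays (s) for the
#'   puncta pool, analogous to the PM delays.
#' @return a `sensor_kinetics` list.
#' @export
sensor_kinetics <- function(depletion_delay = 0, depletion_rate = 0,
                            floor = 1, recovery_delay = 0, recovery_rate = 0,
                            plateau = 1, overshoot_amp = 0,
                            overshoot_decay = 0, puncta_fraction = 0,
                            puncta_depletion_delay = 0,
                            puncta_recovery_delay = 0) {
  p <- list(depletion_delay = depletion_delay, depletion_rate = depletion_rate,
            floor = floor, recovery_delay = recovery_delay,
            recovery_rate = recovery_rate, plateau = plateau,
            overshoot_amp = overshoot_amp, overshoot_decay = overshoot_decay,
            puncta_fraction = puncta_fraction,
            puncta_depletion_delay = puncta_depletion_delay,
            puncta_recovery_delay = puncta_recovery_delay)
  if (any(unlist(p[c("depletion_delay", "depletion_rate", "recovery_delay",
                     "recovery_rate", "overshoot_amp", "overshoot_decay",
                     "puncta_fraction")]) < 0))
    stop("rates, delays and amplitudes must be >= 0")
  if (floor < 0 || floor > plateau || plateau > 1 + overshoot_amp)
    stop("need 0 <= floor <= plateau <= 1 + overshoot_amp")
  if (puncta_fraction > 1) stop("puncta_fraction must be <= 1")
  structure(p, class = "sensor_kinetics")
}

#' Kinetic model of a hypoxia/reoxygenation (or ATP-inhibition) experiment
#'
#' Container for the stress timeline and one [sensor_kinetics()] per sensor.
#'
#' @param t_hypoxia stress onset time (s); must precede `t_reoxy`.
#' @param t_reoxy reoxygenation (washout) time (s).
#' @param sensors named list of [sensor_kinetics()].
#' @return an object of class `kinetic_model`.
#' @seealso [default_kinetic_model()] for the shipped defaults.
#' @export
kinetic_model <- function(t_hypoxia, t_reoxy, sensors) {
  if (!(t_hypoxia < t_reoxy)) stop("t_hypoxia must be < t_reoxy")
  if (is.null(names(sensors)) || any(names(sensors) == ""))
    stop("sensors must be a named list")
  sensors <- lapply(sensors, function(s)
    if (inherits(s, "sensor_kinetics")) s else do.call(sensor_kinetics, s))
  structure(list(t_hypoxia = t_hypoxia, t_reoxy = t_reoxy, sensors = sensors),
            class = "kinetic_model")
}

#' Default kinetic model
#'
#' The shipped stated world: 90 frames at 60 s/frame, stress onset at frame
#' 10 (600 s), reoxygenation at frame 60 (3600 s). Depletion completes
#' within ~30-60 min with sensor-specific delays ordering Lgl first, then
#' PIP2, then PI4P; recovery happens within ~10 min ordering PI4P first,
#' then PIP2, then Lgl. The PI4P reporter additionally shows a transient
#' early-hypoxia overshoot (amplitude 0.15, a free choice: only the
#' existence of the transient is established) and an intracellular puncta
#' pool that empties before PM PI4P and refills after it. `ATP` is an
#' intensimetric cytosolic sensor dropping to a 0.2 floor within 10-20 min;
#' `dye` is a PM dye with constant occupancy used to drive masks.
#'
#' @param t_hypoxia,t_reoxy stress timeline (s).
#' @return a [kinetic_model()].
#' @export
default_kinetic_model <- function(t_hypoxia = 600, t_reoxy = 3600) {
  kinetic_model(
    t_hypoxia = t_hypoxia, t_reoxy = t_reoxy,
    sensors = list(
      Lgl  = sensor_kinetics(depletion_delay = 60, depletion_rate = 0.0035,
                             floor = 0.05, recovery_delay = 240,
                             recovery_rate = 0.004, plateau = 0.95),
      PIP2 = sensor_kinetics(depletion_delay = 240, depletion_rate = 0.0030,
                             floor = 0.05, recovery_delay = 120,
                             recovery_rate = 0.006, plateau = 1),
      PI4P = sensor_kinetics(depletion_delay = 480, depletion_rate = 0.0022,
                             floor = 0.10, recovery_delay = 30,
                             recovery_rate = 0.008, plateau = 1,
                             overshoot_amp = 0.15, overshoot_decay = 1 / 300,
                             puncta_fraction = 0.25,
                             puncta_depletion_delay = 120,
                             puncta_recovery_delay = 300),
      ATP  = sensor_kinetics(depletion_delay = 0, depletion_rate = 0.004,
                             floor = 0.2, recovery_delay = 60,
                             recovery_rate = 0.006, plateau = 1),
      dye  = sensor_kinetics()))
}

# Continuous overshoot pulse: 0 at s = 0, peaks at amp, decays with rate k.
overshoot_pulse <- function(s, amp, k) {
  if (amp <= 0 || k <= 0) return(rep(0, length(s)))
  tau <- 1 / k
  ifelse(s > 0, amp * (s / tau) * exp(1 - s / tau), 0)
}

occupancy_eval <- function(s, t_hyp, t_reoxy, t) {
  t_on <- t_hyp + s$depletion_delay
  t_ron <- t_reoxy + s$recovery_delay
  base <- function(tt) 1 + overshoot_pulse(tt - t_hyp, s$overshoot_amp,
                                           s$overshoot_decay)
  dec <- function(tt) {
    v_on <- base(t_on)
    s$floor + (v_on - s$floor) * exp(-s$depletion_rate * pmax(tt - t_on, 0))
  }
  pre_rec <- function(tt) ifelse(tt < t_on, base(tt), dec(tt))
  v_ron <- pre_rec(t_ron)
  rec <- function(tt) s$plateau + (v_ron - s$plateau) *
    exp(-s$recovery_rate * pmax(tt - t_ron, 0))
  ifelse(t < t_ron, pre_rec(t), rec(t))
}

#' Evaluate sensor occupancy at given times
#'
#' @param model a [kinetic_model()].
#' @param sensor sensor name present in the model.
#' @param t time(s) in seconds (vectorized).
#' @param pool `"pm"` for the plasma-membrane pool, `"puncta"` for the
#'   intracellular puncta pool (same shape, puncta-specific delays, no
#'   overshoot).
#' @return occupancy fraction(s) in `[0, 1 + overshoot_amp]`.
#' @export
simulate_occupancy <- function(model, sensor, t, pool = c("pm", "puncta")) {
  pool <- match.arg(pool)
  s <- model$sensors[[sensor]]
  if (is.null(s))
    stop(sprintf("unknown sensor '%s' (model has: %s)", sensor,
                 paste(names(model$sensors), collapse = ", ")))
  if (pool == "puncta") {
    s <- utils::modifyList(s, list(depletion_delay = s$puncta_depletion_delay,
                                   recovery_delay = s$puncta_recovery_delay,
                                   overshoot_amp = 0))
    class(s) <- "sensor_kinetics"
  }
  occupancy_eval(s, model$t_hypoxia, model$t_reoxy, t)
}

#' Half-transition time of a sensor's occupancy curve
#'
#' The half-depletion time is when occupancy first crosses halfway between
#' the pre-stress baseline (1) and `floor`; the half-recovery time is the
#' crossing halfway between the occupancy at recovery onset and `plateau`.
#' Found by bisection on the evaluated curve, so overshoot and delays are
#' honoured.
#'
#' @param model a [kinetic_model()].
#' @param sensor sensor name.
#' @param phase `"depletion"` or `"recovery"`.
#' @return crossing time in seconds (absolute), or `NA` if the curve never
#'   crosses.
#' @export
occupancy_halftime <- function(model, sensor, phase = c("depletion", "recovery")) {
  phase <- match.arg(phase)
  s <- model$sensors[[sensor]]
  if (is.null(s)) stop(sprintf("unknown sensor '%s'", sensor))
  f <- function(t) simulate_occupancy(model, sensor, t)
  if (phase == "depletion") {
    target <- (1 + s$floor) / 2
    lo <- model$t_hypoxia; hi <- model$t_reoxy + s$recovery_delay
    if (f(hi) > target || s$depletion_rate <= 0) return(NA_real_)
    g <- function(t) f(t) - target
  } else {
    t_ron <- model$t_reoxy + s$recovery_delay
    v0 <- f(t_ron)
    target <- (v0 + s$plateau) / 2
    lo <- t_ron; hi <- t_ron + 1e6
    if (s$recovery_rate <= 0 || s$plateau <= v0) return(NA_real_)
    g <- function(t) target - f(t)
  }
  stats::uniroot(g, c(lo, hi), tol = 1e-6)$root
}
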