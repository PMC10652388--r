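#' Ditch test pavement
#'
#' The ditch pavement used in the obstacle-traversal study: a 2.5 m flat
#' approach, a 100 mm wide x 50 mm deep ditch, and a 1.4 m flat run-out
#' (total 4.0 m; the profile returns to grade).
#'
#' @param approach,rear flat section lengths (m).
#' @param width,depth ditch width and depth (m).
#' @return a [road_profile()].
#' @export
build_ditch_profile <- function(approach = 2.5, width = 0.1, depth = 0.05,
                                rear = 1.4) {
  road_profile(data.frame(
    type = c("flat", "ditch", "flat"),
    length = c(approach, width, rear),
    depth = c(NA, depth, NA),
    height = c(NA, NA, NA)))
}

#' Step test pavement
#'
#' The step pavement: 1.4 m flat approach, a 40 mm rise, a 0.7 m plateau,
#' a 30 mm drop, and a 2.0 m run-out; net elevation change +10 mm.
#'
#' @param approach,plateau,rear flat section lengths (m).
#' @param up,down step heights (m).
#' @return a [road_profile()].
#' @export
build_step_profile <- function(approach = 1.4, up = 0.04, plateau = 0.7,
                               down = 0.03, rear = 2.0) {
  road_profile(data.frame(
    type = c("flat", "step_up", "flat", "step_down", "flat"),
    length = c(approach, 0, plateau, 0, rear),
    depth = c(NA, NA, NA, NA, NA),
    height = c(NA, up, NA, down, NA)))
}

#' Obstacle events of a constant-speed traversal
#'
#' Kinematics of both axles crossing the profile's obstacle features at
#' constant speed: each non-flat segment produces one event per axle, the
#' rear axle lagging the front by `wheelbase / speed`.
#'
#' @param profile a [road_profile()].
#' @param speed travel speed (m/s), > 0.
#' @param wheelbase front-rear axle distance (m).
#' @return data.frame sorted by time: `time` (s), `axle` (`"front"` /
#'   `"rear"`), `type`, `magnitude` (feature depth or height, m),
#'   `position` (m, feature start).
#' @export
traversal_events <- function(profile, speed, wheelbase = 0.5) {
  if (speed <= 0) stop_wheelride("speed must be > 0", "wheelride_bad_input")
  s <- profile$segments
  pos <- cumsum(c(0, s$length))[seq_len(nrow(s))]
  feat <- s$type != "flat"
  if (!any(feat))
    return(data.frame(time = numeric(0), axle = character(0), type = character(0),
                      magnitude = numeric(0), position = numeric(0),
                      stringsAsFactors = FALSE))
  mag <- ifelse(s$type == "ditch", s$depth, s$height)[feat]
  p <- pos[feat]; ty <- s$type[feat]
  ev <- rbind(
    data.frame(time = p / speed, axle = "front", type = ty, magnitude = mag,
               position = p, stringsAsFactors = FALSE),
    data.frame(time = p / speed + wheelbase / speed, axle = "rear", type = ty,
               magnitude = mag, position = p, stringsAsFactors = FALSE))
  ev[order(ev$time), , drop = FALSE]
}

default_location_gains <- function() {
  list(frame = c(x = 1.0, y = 0.3, z = 1.0),
       chest = c(x = 1.0, y = 0.3, z = 1.0),
       head  = c(x = 1.5, y = 0.3, z = 1.1))
}

#' Define a synthetic traversal scenario
#'
#' Bundles a road profile with the kinematic and excitation parameters of a
#' surrogate signal model: each obstacle event excites a damped sinusoid
#' (half-sine first lobe, exponentially decaying ring-down) whose amplitude
#' scales with the feature size, on top of a Gaussian sensor noise floor.
#' Per-location gain vectors encode how strongly each axis responds at each
#' measurement point; the default head fore-aft (pitch) gain exceeds the
#' chest gain, reflecting the looser support of the head.
#'
#' @param profile a [road_profile()].
#' @param speed travel speed (m/s); the study speed is 0.28 m/s.
#' @param wheelbase axle distance (m).
#' @param sample_rate output sampling rate (Hz).
#' @param duration record length (s); default covers the profile plus 2 s.
#' @param pulse_duration first-lobe duration of the event pulse (s).
#' @param damping_ratio pulse decay ratio (0-1).
#' @param base_amplitude vertical peak acceleration per 50 mm of feature
#'   size (m/s^2).
#' @param noise_rms Gaussian noise floor per axis (m/s^2 RMS).
#' @param gains named list of per-location axis gain vectors `c(x=, y=, z=)`.
#' @param seed integer PRNG seed; the generator is R's default Mersenne
#'   Twister, and the seed is recorded in the scenario.
#' @return object of class `traversal_scenario`.
#' @export
traversal_scenario <- function(profile, speed = 0.28, wheelbase = 0.5,
                               sample_rate = 200, duration = NULL,
                               pulse_duration = 0.35, damping_ratio = 0.3,
                               base_amplitude = 1.0, noise_rms = 0.02,
                               gains = default_location_gains(), seed = 1L) {
  if (speed <= 0) stop_wheelride("speed must be > 0", "wheelride_bad_input")
  if (is.null(duration))
    duration <- profile$total_length / speed + wheelbase / speed + 2
  for (loc in MEASUREMENT_LOCATIONS)
    if (is.null(gains[[loc]]) || any(gains[[loc]] < 0))
      stop_wheelride("gains must be given (>= 0) for frame, chest and head",
                     "wheelride_bad_input")
  if (gains$head[["x"]] < gains$chest[["x"]])
    stop_wheelride("head fore-aft gain must be >= chest fore-aft gain",
                   "wheelride_bad_input")
  structure(list(profile = profile, speed = speed, wheelbase = wheelbase,
                 sample_rate = sample_rate, duration = duration,
                 pulse_duration = pulse_duration, damping_ratio = damping_ratio,
                 base_amplitude = base_amplitude, noise_rms = noise_rms,
                 gains = gains, seed = as.integer(seed)),
            class = "traversal_scenario")
}

# Damped sinusoid pulse evaluated at times tau >= 0 after the event:
# first lobe is a half-sine of the given duration, then decaying ring-down.
event_pulse <- function(tau, duration, zeta) {
  wd <- pi / duration
  wn <- wd / sqrt(1 - zeta^2)
  out <- numeric(length(tau))
  pos <- tau >= 0
  out[pos] <- exp(-zeta * wn * tau[pos]) * sin(wd * tau[pos])
  out
}

#' Generate a synthetic triaxial signal for one measurement location
#'
#' Sum of damped event pulses (vertical dominant; fore-aft scaled by the
#' location's pitch gain with alternating sign per axle; lateral low-level)
#' at the traversal event times, plus a seeded Gaussian noise floor. The
#' output is deterministic for a given scenario and seed; the seed is
#' offset per location so the three records are mutually independent.
#'
#' @param scenario a [traversal_scenario()].
#' @param location `"frame"`, `"chest"` or `"head"`.
#' @return a [triaxial_signal()].
#' @export
generate_signal <- function(scenario, location = "chest") {
  location <- match.arg(location, MEASUREMENT_LOCATIONS)
  sc <- scenario
  n <- ceiling(sc$duration * sc$sample_rate)
  t <- (seq_len(n) - 1L) / sc$sample_rate
  ev <- traversal_events(sc$profile, sc$speed, sc$wheelbase)
  g <- sc$gains[[location]]
  ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      amp <- sc$base_amplitude * ev$magnitude[i] / 0.05
      sgn_z <- if (ev$type[i] == "ditch") -1 else if (ev$type[i] == "step_down") -1 else 1
      sgn_x <- if (ev$axle[i] == "front") 1 else -1
      p <- event_pulse(t - ev$time[i], sc$pulse_duration, sc$damping_ratio)
      az <- az + g[["z"]] * amp * sgn_z * p
      ax <- ax + g[["x"]] * 0.6 * amp * sgn_x * p
      ay <- ay + g[["y"]] * 0.2 * amp * p
    }
  }
  loc_offset <- match(location, MEASUREMENT_LOCATIONS)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sc$seed * 13L + loc_offset)
  ax <- ax + rnorm(n, 0, sc$noise_rms)
  ay <- ay + rnorm(n, 0, sc$noise_rms)
  az <- az + rnorm(n, 0, sc$noise_rms)
  triaxial_signal(ax, ay, az, sample_rate = sc$sample_rate, location = location)
}

#' Rescale a signal to a target total vibration value
#'
#' Uniformly scales all three channels so that [evaluate_comfort()] yields
#' the requested av. Because av is homogeneous of degree one in the signal,
#' the required factor is exactly `target_av / current_av`.
#'
#' @param signal a [triaxial_signal()].
#' @param target_av desired total vibration (m/s^2), > 0.
#' @param spec a [weighting_spec()] defining how av is computed.
#' @return rescaled [triaxial_signal()] with attribute `scale_factor`.
#' @export
calibrate_to_target <- function(signal, target_av, spec = weighting_spec()) {
  if (target_av <= 0) stop_wheelride("target_av must be > 0", "wheelride_bad_input")
  current <- evaluate_comfort(signal, spec)$av
  if (current <= 0)
    stop_wheelride("signal has zero total vibration under this weighting",
                   "wheelride_bad_input")
  k <- target_av / current
  out <- signal
  out$ax <- k * signal$ax; out$ay <- k * signal$ay; out$az <- k * signal$az
  attr(out, "scale_factor") <- k
  out
}
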