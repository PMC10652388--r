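#' wheelride: stability and ride comfort of the wheelchair-occupant system
#'
#' Quasi-static rollover/pitch/slip stability limits, ISO 2631-1 weighted-RMS
#' comfort evaluation, and a psychophysical annoyance-rate model, exercised on
#' measured or synthetic triaxial acceleration records of a wheelchair
#' traversing obstacle pavements.
#'
#' Axis convention throughout: x = fore-aft (pitch direction), y = lateral
#' (roll direction), z = vertical. Units are SI; angles are radians internally
#' and degrees in user-facing tables. Weights (Gs, Gu, W) are forces in
#' newtons, the native unit of the moment balances.
#'
#' @keywords internal
#' @importFrom stats integrate uniroot rnorm approx dlnorm plnorm dnorm pnorm
#' @importFrom utils read.csv write.csv modifyList
"_PACKAGE"

MEASUREMENT_LOCATIONS <- c("frame", "chest", "head")

stop_wheelride <- function(msg, class) {
  stop(structure(
    class = c(class, "wheelride_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Construct a triaxial acceleration signal
#'
#' A uniformly sampled three-axis acceleration record at a named measurement
#' location on the wheelchair-occupant system.
#'
#' @param ax,ay,az numeric vectors of equal length (>= 2), acceleration in
#'   m/s^2 along the fore-aft (pitch), lateral (roll) and vertical axes.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param location one of `"frame"`, `"chest"`, `"head"`.
#' @param t0 time of the first sample in seconds.
#' @return object of class `triaxial_signal`.
#' @export
triaxial_signal <- function(ax, ay, az, sample_rate, location = "chest", t0 = 0) {
  location <- match.arg(location, MEASUREMENT_LOCATIONS)
  n <- length(ax)
  if (n < 2L || length(ay) != n || length(az) != n)
    stop_wheelride("ax, ay, az must have equal length >= 2", "wheelride_bad_signal")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop_wheelride("sample_rate must be a positive scalar (Hz)", "wheelride_bad_signal")
  if (!all(is.finite(ax)) || !all(is.finite(ay)) || !all(is.finite(az)))
    stop_wheelride("acceleration channels must be finite", "wheelride_bad_signal")
  structure(
    list(location = location, sample_rate = as.numeric(sample_rate),
         t0 = as.numeric(t0),
         ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az)),
    class = "triaxial_signal")
}

#' @export
print.triaxial_signal <- function(x, ...) {
  n <- length(x$ax)
  cat(sprintf("<triaxial_signal> %s: %d samples @ %g Hz, t = [%g, %g) s\n",
              x$location, n, x$sample_rate, x$t0, x$t0 + n / x$sample_rate))
  invisible(x)
}

#' @export
length.triaxial_signal <- function(x) length(x$ax)

#' Sample times of a signal
#' @param signal a [triaxial_signal()].
#' @return numeric vector of sample times (s).
#' @export
signal_time <- function(signal) {
  signal$t0 + (seq_len(length(signal$ax)) - 1L) / signal$sample_rate
}

#' @export
as.data.frame.triaxial_signal <- function(x, ...) {
  n <- length(x$ax)
  data.frame(time = x$t0 + (seq_len(n) - 1L) / x$sample_rate,
             ax = x$ax, ay = x$ay, az = x$az)
}

#' Validate and regularize a raw acceleration record
#'
#' Checks a raw tabular record (columns `time`, `ax`, `ay`, `az`) for a
#' strictly increasing, near-uniform time base, infers the sample rate, and
#' resamples onto an exactly uniform grid by linear interpolation. Records
#' whose time-step jitter reaches 1% of the nominal step are rejected: such
#' gaps indicate dropped samples, which interpolation would silently smear.
#'
#' @param raw data.frame with columns `time` (s) and `ax`, `ay`, `az` (m/s^2).
#' @param location measurement location label, see [triaxial_signal()].
#' @return a [triaxial_signal()] on a uniform grid.
#' @export
validate_signal <- function(raw, location = "chest") {
  need <- c("time", "ax", "ay", "az")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop_wheelride(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
                   "wheelride_parse_error")
  t <- as.numeric(raw$time)
  if (length(t) < 2L)
    stop_wheelride("need at least 2 samples", "wheelride_bad_signal")
  dt <- diff(t)
  if (any(dt <= 0))
    stop_wheelride("time must be strictly increasing", "wheelride_bad_signal")
  step <- stats::median(dt)
  dev <- max(abs(dt - step))
  if (dev >= 0.01 * step)
    stop_wheelride(sprintf(
      "non-uniform time base: max step deviation %.3g s is >= 1%% of nominal step %.3g s",
      dev, step), "wheelride_bad_signal")
  fs <- 1 / step
  n <- length(t)
  tu <- t[1] + (seq_len(n) - 1L) * step
  interp <- function(y) stats::approx(t, as.numeric(y), xout = tu, rule = 2)$y
  triaxial_signal(interp(raw$ax), interp(raw$ay), interp(raw$az),
                  sample_rate = fs, location = location, t0 = t[1])
}

#' Rollover-analysis plant parameters
#'
#' Parameter set for the quasi-static roll stability model: sprung/unsprung
#' weights, track width, suspension and tire stiffnesses, and the heights and
#' lateral offsets of the mass centers and roll center.
#'
#' @param Gs sprung weight (N).
#' @param Gu unsprung weight (N).
#' @param B track width (m).
#' @param m lateral distance from suspension spring to the longitudinal
#'   symmetry plane (m).
#' @param n lateral distance from tire to the symmetry plane (m).
#' @param ks suspension spring (linear) stiffness (N/m).
#' @param kt tire vertical stiffness (N/m).
#' @param h height of the sprung mass center above the road plane (m).
#' @param h1 distance from the sprung mass center down to the roll center (m).
#' @param h3 equivalent height of the unsprung mass center (m).
#' @param S1,S2,S3 lateral offsets of the unsprung mass center, roll center
#'   and sprung mass center from the symmetry plane (m).
#' @return object of class `roll_plant` with derived fields `G` (total
#'   weight), `hg` (equivalent whole-vehicle mass-center height,
#'   `(Gu*h3 + Gs*h)/G`), `h2 = h - h1` (roll-center height), `kl` (one-side
#'   suspension line stiffness) and `kr` (combined suspension roll stiffness).
#' @export
roll_plant <- function(Gs, Gu, B, m, n, ks, kt, h, h1, h3,
                       S1 = 0, S2 = 0, S3 = 0) {
  if (Gs <= 0 || Gu <= 0) stop_wheelride("weights must be > 0", "wheelride_bad_plant")
  if (B <= 0 || n <= 0) stop_wheelride("B and n must be > 0", "wheelride_bad_plant")
  if (m < 0) stop_wheelride("m must be >= 0", "wheelride_bad_plant")
  if (ks <= 0 || kt <= 0) stop_wheelride("stiffnesses must be > 0", "wheelride_bad_plant")
  if (!(h >= h1 && h1 >= 0)) stop_wheelride("need h >= h1 >= 0", "wheelride_bad_plant")
  if (h3 <= 0) stop_wheelride("h3 must be > 0", "wheelride_bad_plant")
  if (max(abs(c(S1, S2, S3))) >= B / 2)
    stop_wheelride("lateral offsets must satisfy |S| < B/2", "wheelride_bad_plant")
  G <- Gs + Gu
  kl <- suspension_line_stiffness(ks, m, n)
  plant <- list(Gs = Gs, Gu = Gu, B = B, m = m, n = n, ks = ks, kt = kt,
                h = h, h1 = h1, h2 = h - h1, h3 = h3,
                S1 = S1, S2 = S2, S3 = S3,
                G = G, hg = (Gu * h3 + Gs * h) / G,
                kl = kl, kr = suspension_roll_stiffness(kl, B))
  structure(plant, class = "roll_plant")
}

#' @export
print.roll_plant <- function(x, ...) {
  cat(sprintf("<roll_plant> G = %.1f N (Gs %.1f / Gu %.1f), B = %.3f m, hg = %.3f m\n",
              x$G, x$Gs, x$Gu, x$B, x$hg))
  cat(sprintf("  ks = %g N/m, kt = %g N/m  ->  kl = %g N/m, kr = %g N*m/rad\n",
              x$ks, x$kt, x$kl, x$kr))
  invisible(x)
}

#' Pitch-analysis plant parameters
#'
#' @param a horizontal distance from the system mass center to the rear-wheel
#'   axis (m).
#' @param h mass-center height (m).
#' @param L front-rear wheelbase (m).
#' @param mu1 rolling friction coefficient, tire-road.
#' @param mu2 static friction coefficient, tire-road.
#' @param W total weight Gs + Gu (N).
#' @return object of class `pitch_plant`.
#' @export
pitch_plant <- function(a, h, L, mu1, mu2, W = NA_real_) {
  if (L <= 0 || h <= 0) stop_wheelride("L and h must be > 0", "wheelride_bad_plant")
  if (a < 0 || a > L) stop_wheelride("need 0 <= a <= L", "wheelride_bad_plant")
  if (mu1 < 0 || mu1 > 1.5 || mu2 < 0 || mu2 > 1.5)
    stop_wheelride("friction coefficients must lie in [0, 1.5]", "wheelride_bad_plant")
  structure(list(a = a, h = h, L = L, mu1 = mu1, mu2 = mu2, W = W),
            class = "pitch_plant")
}

#' @export
print.pitch_plant <- function(x, ...) {
  cat(sprintf("<pitch_plant> a = %.3f m, h = %.3f m, L = %.3f m, mu1 = %.2f, mu2 = %.2f\n",
              x$a, x$h, x$L, x$mu1, x$mu2))
  invisible(x)
}

#' Piecewise road elevation profile
#'
#' Ordered sequence of longitudinal segments, each flat or carrying one
#' obstacle feature (a ditch of given width and depth, or an up/down step).
#'
#' @param segments a data.frame with columns `type` (one of `"flat"`,
#'   `"ditch"`, `"step_up"`, `"step_down"`), `length` (m; for a ditch the
#'   length equals its width), and feature columns `depth` / `height` (m,
#'   `NA` where not applicable).
#' @return object of class `road_profile`.
#' @export
road_profile <- function(segments) {
  need <- c("type", "length")
  if (!all(need %in% names(segments)))
    stop_wheelride("segments need columns type, length", "wheelride_bad_profile")
  if (!all(segments$type %in% c("flat", "ditch", "step_up", "step_down")))
    stop_wheelride("unknown segment type", "wheelride_bad_profile")
  if (any(segments$length <= 0 & segments$type != "step_up" & segments$type != "step_down"))
    stop_wheelride("segment lengths must be > 0", "wheelride_bad_profile")
  if (!"depth" %in% names(segments)) segments$depth <- NA_real_
  if (!"height" %in% names(segments)) segments$height <- NA_real_
  if (any(segments$type == "ditch" & !(segments$depth > 0)))
    stop_wheelride("ditch segments need depth > 0", "wheelride_bad_profile")
  if (any(segments$type %in% c("step_up", "step_down") & !(segments$height > 0)))
    stop_wheelride("step segments need height > 0", "wheelride_bad_profile")
  structure(list(segments = segments, total_length = sum(segments$length)),
            class = "road_profile")
}

#' @export
print.road_profile <- function(x, ...) {
  cat(sprintf("<road_profile> %d segments, total length %.3f m, net elevation %+.3f m\n",
              nrow(x$segments), x$total_length, profile_net_elevation(x)))
  invisible(x)
}

#' Net elevation change over a road profile
#' @param profile a [road_profile()].
#' @return net elevation change (m); ditches return to grade, steps do not.
#' @export
profile_net_elevation <- function(profile) {
  s <- profile$segments
  sum(ifelse(s$type == "step_up", s$height,
             ifelse(s$type == "step_down", -s$height, 0)))
}

#' Read a roll/pitch plant configuration from JSON or YAML
#'
#' The file must contain exactly the constructor arguments of [roll_plant()]
#' or [pitch_plant()]; unknown keys are rejected so that typos cannot be
#' silently ignored.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @param type `"roll"` or `"pitch"`.
#' @return a `roll_plant` or `pitch_plant`.
#' @export
read_plant_config <- function(path, type = c("roll", "pitch")) {
  type <- match.arg(type)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ctor <- if (type == "roll") roll_plant else pitch_plant
  allowed <- names(formals(ctor))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop_wheelride(paste0("unknown plant key(s): ", paste(unknown, collapse = ", ")),
                   "wheelride_parse_error")
  do.call(ctor, cfg)
}
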