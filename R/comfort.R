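#' Weighting and direction-factor specification
#'
#' ISO 2631-1 seated-body configuration: the lateral and fore-aft axes use
#' the Wd weighting with direction factor 1.4, the vertical axis uses Wk
#' with factor 1.0; the analysis band is 0.5-80 Hz. `weighting = "none"`
#' selects the identity weighting (raw RMS with direction factors only),
#' provided because published total-vibration tables do not always state
#' whether spectral weighting was applied.
#'
#' @param weighting `"iso"` or `"none"`.
#' @param kx,ky,kz direction factors for the fore-aft, lateral and vertical
#'   axes.
#' @param band analysis frequency band (Hz), `c(low, high)`.
#' @return object of class `weighting_spec`.
#' @export
weighting_spec <- function(weighting = c("iso", "none"),
                           kx = 1.4, ky = 1.4, kz = 1.0,
                           band = c(0.5, 80)) {
  weighting <- match.arg(weighting)
  if (any(c(kx, ky, kz) <= 0))
    stop_wheelride("direction factors must be > 0", "wheelride_bad_input")
  if (band[1] >= band[2])
    stop_wheelride("band must satisfy low < high", "wheelride_bad_input")
  structure(list(weighting = weighting, kx = kx, ky = ky, kz = kz,
                 band = band,
                 filters = c(x = "Wd", y = "Wd", z = "Wk")),
            class = "weighting_spec")
}

# Analog cascade parameters (corner frequencies in Hz, resonance Q) of the
# principal-axis weightings: band-limiting two-pole high/low pass (f1, f2,
# Q = 1/sqrt(2)), acceleration-velocity transition (f3, f4, Q4), and for Wk
# an upward-step section (f5, f6, Q5, Q6).
iso_weighting_params <- function(filter = c("Wk", "Wd")) {
  switch(match.arg(filter),
    Wk = list(f1 = 0.4, f2 = 100, f3 = 12.5, f4 = 12.5, Q4 = 0.63,
              f5 = 2.37, Q5 = 0.91, f6 = 3.35, Q6 = 0.91),
    Wd = list(f1 = 0.4, f2 = 100, f3 = 2.0, f4 = 2.0, Q4 = 0.63,
              f5 = Inf, Q5 = 1, f6 = Inf, Q6 = 1))
}

#' Analog weighting-filter gain
#'
#' Magnitude of the Wk or Wd frequency-weighting transfer function at given
#' frequencies, evaluated from the analog cascade. Matches the third-octave
#' gain tables published with the standard (e.g. Wk: 0.967 at 4 Hz, 1.036 at
#' 8 Hz; Wd: 1.011 at 1 Hz, 0.890 at 2 Hz).
#'
#' @param freq frequencies (Hz).
#' @param filter `"Wk"` or `"Wd"`.
#' @return gain magnitudes (dimensionless).
#' @export
iso_weighting_gain <- function(freq, filter = c("Wk", "Wd")) {
  p <- iso_weighting_params(filter)
  s <- 2i * pi * freq
  w1 <- 2 * pi * p$f1; w2 <- 2 * pi * p$f2
  w3 <- 2 * pi * p$f3; w4 <- 2 * pi * p$f4
  Hh <- s^2 / (s^2 + sqrt(2) * w1 * s + w1^2)
  Hl <- w2^2 / (s^2 + sqrt(2) * w2 * s + w2^2)
  Ht <- (1 + s / w3) / (1 + s / (p$Q4 * w4) + (s / w4)^2)
  Hs <- if (is.finite(p$f5)) {
    w5 <- 2 * pi * p$f5; w6 <- 2 * pi * p$f6
    (s^2 + w5 * s / p$Q5 + w5^2) / (s^2 + w6 * s / p$Q6 + w6^2)
  } else 1
  Mod(Hh * Hl * Ht * Hs)
}

# Analog second-order sections of a weighting filter, each as
# list(b = num coeffs (s^2, s, 1), a = den coeffs, fc = prewarp frequency Hz).
iso_weighting_sections <- function(filter) {
  p <- iso_weighting_params(filter)
  w1 <- 2 * pi * p$f1; w2 <- 2 * pi * p$f2
  w3 <- 2 * pi * p$f3; w4 <- 2 * pi * p$f4
  sec <- list(
    list(b = c(1, 0, 0), a = c(1, sqrt(2) * w1, w1^2), fc = p$f1),
    list(b = c(0, 0, w2^2), a = c(1, sqrt(2) * w2, w2^2), fc = p$f2),
    list(b = c(0, w4^2 / w3, w4^2), a = c(1, w4 / p$Q4, w4^2), fc = p$f4))
  if (is.finite(p$f5)) {
    w5 <- 2 * pi * p$f5; w6 <- 2 * pi * p$f6
    sec <- c(sec, list(
      list(b = c(1, w5 / p$Q5, w5^2), a = c(1, w6 / p$Q6, w6^2), fc = p$f6)))
  }
  sec
}

# Bilinear transform of one analog biquad with prewarping at fc. A corner
# at or above Nyquist cannot be prewarped; fall back to the plain transform
# (the section then degenerates gracefully towards an all-pass).
bilinear_biquad <- function(b, a, fs, fc) {
  wc <- 2 * pi * fc
  K <- if (fc < 0.499 * fs) wc / tan(wc / (2 * fs)) else 2 * fs
  nz <- c(b[1] * K^2 + b[2] * K + b[3],
          -2 * b[1] * K^2 + 2 * b[3],
          b[1] * K^2 - b[2] * K + b[3])
  dz <- c(a[1] * K^2 + a[2] * K + a[3],
          -2 * a[1] * K^2 + 2 * a[3],
          a[1] * K^2 - a[2] * K + a[3])
  list(b = nz / dz[1], a = dz / dz[1])
}

# Digital SOS cascade for Wk/Wd at sampling rate fs.
iso_weighting_sos <- function(filter, fs) {
  lapply(iso_weighting_sections(filter), function(s)
    bilinear_biquad(s$b, s$a, fs, s$fc))
}

apply_sos <- function(x, sos) {
  for (s in sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

#' Apply ISO 2631-1 frequency weighting to a signal
#'
#' Filters each axis of a triaxial record with its weighting filter (x, y:
#' Wd; z: Wk), realized as a cascade of bilinear-discretized second-order
#' sections. With `spec$weighting == "none"` the signal is returned
#' unchanged.
#'
#' @param signal a [triaxial_signal()].
#' @param spec a [weighting_spec()].
#' @return weighted [triaxial_signal()].
#' @export
apply_frequency_weighting <- function(signal, spec = weighting_spec()) {
  if (signal$sample_rate < 2)
    stop_wheelride("sample rate below 2 Hz cannot carry the analysis band",
                   "wheelride_unusable_signal")
  if (spec$weighting == "none") return(signal)
  if (signal$sample_rate < 2 * spec$band[2])
    warning(sprintf(
      "sample rate %g Hz < 2 x band edge %g Hz; weighting band truncated at Nyquist",
      signal$sample_rate, spec$band[2]))
  fs <- signal$sample_rate
  out <- signal
  out$ax <- apply_sos(signal$ax, iso_weighting_sos(spec$filters[["x"]], fs))
  out$ay <- apply_sos(signal$ay, iso_weighting_sos(spec$filters[["y"]], fs))
  out$az <- apply_sos(signal$az, iso_weighting_sos(spec$filters[["z"]], fs))
  out
}

#' Weighted root-mean-square acceleration of one channel
#'
#' `aw = sqrt( (1/T) * integral_0^T a^2(t) dt )`, computed by trapezoidal
#' integration on the uniform sample grid over the window `[0, T)` from the
#' start of the record.
#'
#' @param channel numeric vector, (weighted) acceleration samples (m/s^2).
#' @param sample_rate sampling rate (Hz).
#' @param T analysis window (s); defaults to the full record duration.
#' @param demean subtract the channel mean before integration.
#' @return RMS value (m/s^2).
#' @export
weighted_rms <- function(channel, sample_rate, T = NULL, demean = FALSE) {
  n <- length(channel)
  dur <- (n - 1) / sample_rate
  if (is.null(T)) T <- dur
  if (T <= 0 || T > dur + 1e-12)
    stop_wheelride("window T must satisfy 0 < T <= record duration", "wheelride_bad_input")
  t <- (seq_len(n) - 1L) / sample_rate
  keep <- t <= T + 1e-12
  x <- channel[keep]
  if (demean) x <- x - mean(x)
  sqrt(pracma::trapz(t[keep], x^2) / (t[keep][sum(keep)] - 0))
}

#' Total vibration value
#'
#' Direction-factored Euclidean combination of the three axis RMS values:
#' `av = sqrt(kx^2*awx^2 + ky^2*awy^2 + kz^2*awz^2)`.
#'
#' @param awx,awy,awz per-axis weighted RMS (m/s^2), >= 0.
#' @param spec a [weighting_spec()] carrying the direction factors.
#' @return total vibration av (m/s^2).
#' @export
total_vibration <- function(awx, awy, awz, spec = weighting_spec()) {
  if (any(c(awx, awy, awz) < 0))
    stop_wheelride("axis RMS values must be >= 0", "wheelride_bad_input")
  sqrt((spec$kx * awx)^2 + (spec$ky * awy)^2 + (spec$kz * awz)^2)
}

#' Comfort classification bands
#'
#' The published av bands for seated whole-body vibration, with the ride
#' comfort score C attached to each. Adjacent bands overlap in the source
#' table; [classify_comfort()] resolves the overlap by first match in
#' ascending row order on half-open intervals `[lower, upper)`.
#'
#' @return data.frame with columns `lower`, `upper` (m/s^2), `label`, `C`.
#' @export
comfort_bands <- function() {
  data.frame(
    lower = c(0, 0.315, 0.5, 0.8, 1.25, 2.0),
    upper = c(0.315, 0.630, 1.0, 1.6, 2.50, Inf),
    label = c("Stay comfortable", "Lightly uncomfortable", "Some uncomfortable",
              "Uncomfortable", "Very uncomfortable", "Especially uncomfortable"),
    C = c(1.0, 0.8, 0.6, 0.4, 0.2, 0),
    stringsAsFactors = FALSE)
}

#' Classify a total vibration value
#'
#' @param av total vibration (m/s^2), >= 0.
#' @param bands band table, see [comfort_bands()].
#' @return list with `label` and ride-comfort score `C`.
#' @export
classify_comfort <- function(av, bands = comfort_bands()) {
  if (av < 0) stop_wheelride("av must be >= 0", "wheelride_bad_input")
  hit <- which(av >= bands$lower & av < bands$upper)
  if (!length(hit))
    stop_wheelride("av not covered by the band table", "wheelride_bad_input")
  i <- hit[1L]
  list(label = bands$label[i], C = bands$C[i])
}

#' Evaluate ride comfort of a triaxial record
#'
#' Full objective pipeline: frequency weighting, per-axis weighted RMS over
#' the analysis window, direction-factored total vibration, and band
#' classification.
#'
#' @param signal a [triaxial_signal()].
#' @param spec a [weighting_spec()].
#' @param bands band table, see [comfort_bands()].
#' @param T analysis window (s), default full record.
#' @param demean subtract channel means before the RMS integral.
#' @return object of class `comfort_result`: `location`, `awx`, `awy`,
#'   `awz`, `av` (m/s^2), `label`, `C`, `weighting`.
#' @export
evaluate_comfort <- function(signal, spec = weighting_spec(),
                             bands = comfort_bands(), T = NULL, demean = FALSE) {
  w <- apply_frequency_weighting(signal, spec)
  fs <- w$sample_rate
  awx <- weighted_rms(w$ax, fs, T, demean)
  awy <- weighted_rms(w$ay, fs, T, demean)
  awz <- weighted_rms(w$az, fs, T, demean)
  av <- total_vibration(awx, awy, awz, spec)
  cls <- classify_comfort(av, bands)
  structure(list(location = signal$location,
                 awx = awx, awy = awy, awz = awz, av = av,
                 label = cls$label, C = cls$C,
                 weighting = spec$weighting),
            class = "comfort_result")
}

#' @export
print.comfort_result <- function(x, ...) {
  cat(sprintf("<comfort_result> %s (weighting: %s)\n", x$location, x$weighting))
  cat(sprintf("  aw (x,y,z) = %.4f, %.4f, %.4f m/s^2\n", x$awx, x$awy, x$awz))
  cat(sprintf("  av = %.4f m/s^2  ->  %s (C = %.1f)\n", x$av, x$label, x$C))
  invisible(x)
}
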