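#' One-side suspension line stiffness
#'
#' Vertical stiffness of a single suspension side as felt at the wheel plane:
#' a spring of stiffness `ks` mounted at lateral distance `m` from the
#' symmetry plane acts through the lever ratio `m/n` onto the tire at
#' distance `n`, so the equivalent line stiffness is `kl = 2*ks*(m/n)^2`.
#'
#' @param ks suspension spring stiffness (N/m), > 0.
#' @param m spring-to-midplane distance (m), >= 0.
#' @param n tire-to-midplane distance (m), > 0.
#' @return line stiffness kl (N/m).
#' @export
suspension_line_stiffness <- function(ks, m, n) {
  if (n <= 0) stop_wheelride("degenerate geometry: n must be > 0", "wheelride_singular_geometry")
  if (ks <= 0) stop_wheelride("ks must be > 0", "wheelride_bad_plant")
  if (m < 0) stop_wheelride("m must be >= 0", "wheelride_bad_plant")
  2 * ks * (m / n)^2
}

#' Combined suspension roll stiffness
#'
#' Restoring moment per radian of body roll from the two equivalent
#' suspension springs at +/- B/2: a roll increment dPhi deforms each spring
#' by (B/2) dPhi, giving the restoring moment kl*(B/2)^2 dPhi per side, i.e.
#' `kr = kl * B^2 / 2` for the pair.
#'
#' @param kl line stiffness from [suspension_line_stiffness()] (N/m), >= 0.
#' @param B track width (m), > 0.
#' @return roll stiffness kr (N*m/rad).
#' @export
suspension_roll_stiffness <- function(kl, B) {
  if (B <= 0) stop_wheelride("B must be > 0", "wheelride_bad_plant")
  if (kl < 0) stop_wheelride("kl must be >= 0", "wheelride_bad_plant")
  kl * B^2 / 2
}

#' Static tire deflection on level ground
#'
#' Each of the two tire sides carries half the total weight, so the static
#' deflection is `(Gu + Gs) / (2 * kt)`.
#'
#' @param plant a [roll_plant()].
#' @return static deflection Delta0 (m).
#' @export
static_tire_deflection <- function(plant) {
  plant$G / (2 * plant$kt)
}

#' Normal tire loads on a lateral slope
#'
#' Load transfer on a slope of angle `alpha` with unsprung roll `phi1`:
#' `F1 = G*cos(alpha)/2 - kt*B*phi1/2` (upslope, unloading side) and
#' `F2 = G*cos(alpha)/2 + kt*B*phi1/2` (downslope side). Their sum equals
#' the slope-normal gravity component `G*cos(alpha)` identically.
#'
#' @param plant a [roll_plant()].
#' @param alpha slope angle (rad), |alpha| < pi/2.
#' @param phi1 unsprung roll displacement (rad).
#' @return list with `F1`, `F2` (N) and logical `lift_off` (TRUE when F1 < 0,
#'   i.e. the state is beyond the validity of ground contact on both sides).
#' @export
tire_loads_on_slope <- function(plant, alpha, phi1) {
  if (abs(alpha) >= pi / 2)
    stop_wheelride("|alpha| must be < pi/2", "wheelride_bad_input")
  half <- plant$G * cos(alpha) / 2
  dF <- plant$kt * plant$B * phi1 / 2
  list(F1 = half - dF, F2 = half + dF, lift_off = (half - dF) < 0)
}

#' Quasi-static roll response on a slope
#'
#' Solves the coupled moment balances for the unsprung (tire-level) roll
#' `phi1` and the sprung roll `phi2` (relative to the unsprung mass, i.e.
#' the suspension deformation angle) at slope angle `alpha`:
#' \itemize{
#'   \item sprung-body moment about the roll center:
#'     `kr*phi2 = Gs*(h*sin(alpha) + cos(alpha)*(S3 - S2))`;
#'   \item whole-system moment about the downslope contact line, with
#'     first-order roll-induced lateral shifts of both mass centers:
#'     `kt*B^2/2*phi1 = G*hg*sin(alpha) +
#'        cos(alpha)*(Gs*S3 + Gu*S1 + G*hg*phi1 + Gs*h1*phi2)`.
#' }
#' The system is linear in (phi1, phi2) at fixed alpha and solved exactly;
#' residuals of both balances are returned for verification.
#'
#' @param plant a [roll_plant()].
#' @param alpha slope angle (rad).
#' @return list with `phi1`, `phi2` (rad) and `residuals` (N*m) of the two
#'   moment equations.
#' @export
sprung_roll_response <- function(plant, alpha) {
  p <- plant
  ca <- cos(alpha); sa <- sin(alpha)
  phi2 <- p$Gs * (p$h * sa + ca * (p$S3 - p$S2)) / p$kr
  den <- p$kt * p$B^2 / 2 - p$G * p$hg * ca
  if (den <= 0)
    stop_wheelride(
      "singular geometry: tire roll stiffness kt*B^2/2 does not exceed the gravity lean moment G*hg*cos(alpha)",
      "wheelride_singular_geometry")
  phi1 <- (p$G * p$hg * sa + ca * (p$Gs * p$S3 + p$Gu * p$S1 + p$Gs * p$h1 * phi2)) / den
  r1 <- p$kr * phi2 - p$Gs * (p$h * sa + ca * (p$S3 - p$S2))
  r2 <- p$kt * p$B^2 / 2 * phi1 -
    (p$G * p$hg * sa + ca * (p$Gs * p$S3 + p$Gu * p$S1 + p$G * p$hg * phi1 + p$Gs * p$h1 * phi2))
  list(phi1 = phi1, phi2 = phi2, residuals = c(roll_center = r1, contact = r2))
}

#' Rollover limit angle
#'
#' Smallest slope angle at which the upslope tire load vanishes (F1 = 0),
#' the quasi-static rollover threshold. The defining condition is solved on
#' the coupled system of [sprung_roll_response()] and
#' [tire_loads_on_slope()] by bracketing and Brent root-finding
#' (tolerance 1e-10 rad). In the rigid limit (large `ks`, `kt`, zero
#' offsets) the result converges to the tipping angle `atan(B/(2*hg))`.
#'
#' @param plant a [roll_plant()].
#' @param alpha_max upper end of the search bracket (rad).
#' @return limit angle alpha1 (rad); `Inf` with attribute
#'   `status = "stable-in-range"` if no lift-off occurs below `alpha_max`.
#' @export
roll_limit_angle <- function(plant, alpha_max = 89.9 * pi / 180) {
  f <- function(alpha) {
    resp <- sprung_roll_response(plant, alpha)
    tire_loads_on_slope(plant, alpha, resp$phi1)$F1
  }
  lo <- 1e-4
  flo <- f(lo)
  if (flo <= 0) return(lo)
  # march to find a sign change; F1 decreases towards lift-off
  grid <- seq(lo, alpha_max, length.out = 256L)
  fg <- vapply(grid, function(a) tryCatch(f(a), error = function(e) NA_real_), numeric(1))
  idx <- which(!is.na(fg) & fg <= 0)
  if (!length(idx)) {
    if (anyNA(fg))
      stop_wheelride("roll response became singular before lift-off", "wheelride_singular_geometry")
    return(structure(Inf, status = "stable-in-range"))
  }
  i <- idx[1L]
  uniroot(f, c(grid[i - 1L], grid[i]), tol = 1e-10)$root
}

#' Pitch (tip-back) limit angle
#'
#' Uphill slope at which the front-wheel load vanishes: `beta_lim =
#' atan(a/h)`. Depends only on the mass-center position ratio.
#'
#' @param plant a [pitch_plant()].
#' @return limit angle (rad) in `[0, pi/2)`.
#' @export
pitch_limit_angle <- function(plant) {
  atan2(plant$a, plant$h)
}

slip_angle_from_tangent <- function(tangent) {
  structure(abs(atan(tangent)),
            tangent = tangent,
            regime = if (tangent < 0) "friction-dominated" else "normal")
}

#' Maximum uphill slip angle at constant speed
#'
#' Slope beyond which rolling-friction traction can no longer hold the
#' system while climbing at constant speed:
#' `beta1 = atan(mu1*(2*a - L) / (2*h*mu1 - L))`.
#' The magnitude of the angle is returned; when the printed fraction is
#' negative the attribute `regime = "friction-dominated"` marks the sign
#' regime (the sign convention of the slope is not defined by the balance
#' itself).
#'
#' @param plant a [pitch_plant()].
#' @return slip angle (rad, magnitude) with attributes `tangent`, `regime`.
#' @export
uphill_slip_angle <- function(plant) {
  den <- 2 * plant$h * plant$mu1 - plant$L
  if (abs(den) < 1e-12)
    stop_wheelride("singular geometry: 2*h*mu1 = L", "wheelride_singular_geometry")
  slip_angle_from_tangent(plant$mu1 * (2 * plant$a - plant$L) / den)
}

#' Downhill slip angle at constant speed
#'
#' `beta2 = atan((mu1 - mu2)*a / ((mu1 - mu2)*h - L))`; zero whenever the
#' rolling and static friction coefficients coincide. Magnitude returned as
#' for [uphill_slip_angle()].
#'
#' @param plant a [pitch_plant()].
#' @return slip angle (rad, magnitude) with attributes `tangent`, `regime`.
#' @export
downhill_slip_angle <- function(plant) {
  dmu <- plant$mu1 - plant$mu2
  den <- dmu * plant$h - plant$L
  if (abs(den) < 1e-12)
    stop_wheelride("singular geometry: (mu1 - mu2)*h = L", "wheelride_singular_geometry")
  slip_angle_from_tangent(dmu * plant$a / den)
}

#' Stability envelope over a parameter grid
#'
#' Sweeps one or more plant parameters over a rectangular grid and tabulates
#' the four stability angles at every grid point. Parameters are matched by
#' name against the roll plant first, then the pitch plant.
#'
#' @param plant a [roll_plant()] (baseline for the rollover limit).
#' @param pitch a [pitch_plant()] (baseline for pitch/slip limits).
#' @param sweep named list; each element is a numeric vector of values for
#'   that parameter (>= 1 value each).
#' @return data.frame with one row per grid point: swept parameter columns,
#'   `alpha1_deg`, `beta_lim_deg`, `beta1_deg`, `beta2_deg`, `status`
#'   (`"ok"` or the failure reason; angle columns are `NaN` on failure).
#' @export
stability_envelope <- function(plant, pitch, sweep) {
  if (!length(sweep) || is.null(names(sweep)) || any(names(sweep) == ""))
    stop_wheelride("sweep must be a named list of value vectors", "wheelride_bad_input")
  grid <- expand.grid(sweep, KEEP.OUT.ATTRS = FALSE)
  roll_args <- names(formals(roll_plant))
  pitch_args <- names(formals(pitch_plant))
  bad <- setdiff(names(sweep), union(roll_args, pitch_args))
  if (length(bad))
    stop_wheelride(paste0("unknown sweep parameter(s): ", paste(bad, collapse = ", ")),
                   "wheelride_bad_input")
  one <- function(row) {
    rp_args <- plant[intersect(roll_args, names(plant))]
    pp_args <- pitch[setdiff(intersect(pitch_args, names(pitch)), "W")]
    pp_args$W <- pitch$W
    for (nm in names(row)) {
      if (nm %in% roll_args) rp_args[[nm]] <- row[[nm]]
      if (nm %in% pitch_args) pp_args[[nm]] <- row[[nm]]
    }
    tryCatch({
      rp <- do.call(roll_plant, rp_args)
      pp <- do.call(pitch_plant, pp_args)
      deg <- 180 / pi
      data.frame(alpha1_deg = as.numeric(roll_limit_angle(rp)) * deg,
                 beta_lim_deg = pitch_limit_angle(pp) * deg,
                 beta1_deg = as.numeric(uphill_slip_angle(pp)) * deg,
                 beta2_deg = as.numeric(downhill_slip_angle(pp)) * deg,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(alpha1_deg = NaN, beta_lim_deg = NaN, beta1_deg = NaN,
                 beta2_deg = NaN, status = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  }
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) one(as.list(grid[i, , drop = FALSE]))))
  cbind(grid, res)
}
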