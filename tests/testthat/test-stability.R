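test_that("suspension line stiffness follows the lever-squared law", {
  expect_equal(suspension_line_stiffness(1000, 0.2, 0.2), 2000)
  expect_equal(suspension_line_stiffness(1000, 0, 0.2), 0)
  expect_equal(suspension_line_stiffness(800, 0.15, 0.25), 576)
  expect_error(suspension_line_stiffness(1000, 0.2, 0),
               class = "wheelride_singular_geometry")
})

test_that("roll stiffness is the two-spring moment per radian", {
  expect_equal(suspension_roll_stiffness(0, 1), 0)
  expect_equal(suspension_roll_stiffness(2000, 1), 1000)
  # doubling the track quadruples the roll stiffness
  expect_equal(suspension_roll_stiffness(1234, 0.8),
               suspension_roll_stiffness(1234, 0.4) * 4)
})

test_that("static tire deflection is weight over twice the tire stiffness", {
  p <- make_roll_plant(Gs = 450, Gu = 150, kt = 30000)
  expect_equal(static_tire_deflection(p), 0.01)
  p2 <- make_roll_plant(Gs = 900, Gu = 300, kt = 30000)
  expect_equal(static_tire_deflection(p2), 2 * static_tire_deflection(p))
})

test_that("tire loads transfer with roll and conserve the normal resultant", {
  p <- make_roll_plant(Gs = 450, Gu = 150, kt = 30000, B = 0.5)
  rest <- tire_loads_on_slope(p, 0, 0)
  expect_equal(rest$F1, 300)
  expect_equal(rest$F2, 300)
  tl <- tire_loads_on_slope(p, 0, 0.01)
  expect_equal(tl$F1, 225)
  expect_equal(tl$F2, 375)
  expect_false(tl$lift_off)
})

test_that("load conservation F1 + F2 = G cos(alpha) holds across random states", {
  set.seed(101)
  for (i in 1:200) {
    p <- random_roll_plant()
    alpha <- runif(1, -0.6, 0.6)
    phi1 <- runif(1, -0.05, 0.05)
    tl <- tire_loads_on_slope(p, alpha, phi1)
    expect_lt(abs(tl$F1 + tl$F2 - p$G * cos(alpha)) / (p$G * cos(alpha)), 1e-9)
  }
})

test_that("roll response vanishes at zero slope with centered masses", {
  p <- make_roll_plant()
  r <- sprung_roll_response(p, 0)
  expect_equal(r$phi1, 0)
  expect_equal(r$phi2, 0)
})

test_that("roll response satisfies both moment balances", {
  set.seed(21)
  for (i in 1:25) {
    p <- random_roll_plant()
    alpha <- runif(1, 0, 0.3)
    r <- sprung_roll_response(p, alpha)
    scale <- max(p$G * p$hg, p$kr * max(abs(r$phi2), 1e-6))
    expect_lt(max(abs(r$residuals)) / scale, 1e-10)
  }
})

test_that("suspension roll linearizes to Gs*h/kr times alpha with no offsets", {
  p <- make_roll_plant()
  alpha <- 1e-4
  r <- sprung_roll_response(p, alpha)
  expect_equal(r$phi2, p$Gs * p$h / p$kr * alpha, tolerance = 1e-6)
})

test_that("roll limit converges to the rigid tipping angle for stiff plants", {
  p <- make_roll_plant(ks = 1e9, kt = 1e10)
  rigid <- atan(p$B / (2 * p$hg))
  expect_lt(abs(roll_limit_angle(p) - rigid) * 180 / pi, 0.1)
})

test_that("compliance lowers the roll limit below the rigid tipping angle", {
  p <- make_roll_plant()
  a1 <- roll_limit_angle(p)
  rigid <- atan(p$B / (2 * p$hg))
  expect_lt(a1, rigid)
  # brute-force scan of the lift-off condition agrees with the root
  f1 <- function(a) tire_loads_on_slope(p, a, sprung_roll_response(p, a)$phi1)$F1
  grid <- seq(1e-4, 0.6, length.out = 4001)
  scan <- grid[which(vapply(grid, f1, numeric(1)) <= 0)[1]]
  expect_lt(abs(a1 - scan), diff(grid[1:2]))
})

test_that("roll limit falls with mass-center height and rises with track width", {
  p <- make_roll_plant()
  taller <- make_roll_plant(h = p$h * 1.2, h3 = p$h3 * 1.2)
  expect_lt(roll_limit_angle(taller), roll_limit_angle(p))
  wider <- make_roll_plant(B = p$B * 1.2)
  expect_gt(roll_limit_angle(wider), roll_limit_angle(p))
})

test_that("roll limit is invariant under length-up/stiffness-down scaling", {
  p <- make_roll_plant()
  c0 <- 1.7
  scaled <- make_roll_plant(B = p$B * c0, m = p$m * c0, n = p$n * c0,
                            h = p$h * c0, h1 = p$h1 * c0, h3 = p$h3 * c0,
                            ks = p$ks / c0, kt = p$kt / c0)
  expect_equal(roll_limit_angle(scaled), roll_limit_angle(p), tolerance = 1e-7)
})

test_that("an extremely wide stiff plant is stable over the search range", {
  p <- make_roll_plant(B = 0.9, h = 0.12, h1 = 0.02, h3 = 0.05,
                       ks = 1e8, kt = 1e9, n = 0.45, m = 0.4)
  a1 <- roll_limit_angle(p, alpha_max = 20 * pi / 180)
  expect_true(is.infinite(a1))
  expect_identical(attr(a1, "status"), "stable-in-range")
})

test_that("pitch limit angle is arctan(a/h)", {
  expect_equal(pitch_limit_angle(make_pitch_plant(a = 0.5, h = 0.5)), pi / 4)
  expect_equal(pitch_limit_angle(make_pitch_plant(a = 0)), 0)
  expect_equal(pitch_limit_angle(make_pitch_plant(a = 0.2, h = 0.8)) * 180 / pi,
               14.036, tolerance = 1e-4)
  # depends only on the ratio a/h
  expect_equal(pitch_limit_angle(make_pitch_plant(a = 0.1, h = 0.4, L = 0.5)),
               pitch_limit_angle(make_pitch_plant(a = 0.2, h = 0.8)))
})

test_that("pitch limit is monotone in the mass-center position", {
  hs <- seq(0.4, 1.2, by = 0.2)
  b <- vapply(hs, function(h) pitch_limit_angle(make_pitch_plant(h = h)), numeric(1))
  expect_true(all(diff(b) < 0))
  as_ <- seq(0.05, 0.45, by = 0.1)
  b2 <- vapply(as_, function(a) pitch_limit_angle(make_pitch_plant(a = a)), numeric(1))
  expect_true(all(diff(b2) > 0))
})

test_that("uphill slip angle vanishes without friction or with a centered axle", {
  expect_equal(as.numeric(uphill_slip_angle(make_pitch_plant(mu1 = 0))), 0)
  expect_equal(as.numeric(uphill_slip_angle(make_pitch_plant(a = 0.25, L = 0.5,
                                                             mu1 = 0.9))), 0)
  p <- make_pitch_plant(mu1 = 0.8, a = 0.3, L = 0.5, h = 0.6)
  expect_equal(as.numeric(uphill_slip_angle(p)) * 180 / pi, 9.865, tolerance = 1e-3)
  expect_error(uphill_slip_angle(make_pitch_plant(h = 0.25, mu1 = 1.0)),
               class = "wheelride_singular_geometry")
})

test_that("downhill slip angle vanishes when the friction coefficients agree", {
  expect_equal(as.numeric(downhill_slip_angle(make_pitch_plant(mu1 = 0.7, mu2 = 0.7))), 0)
  expect_equal(as.numeric(downhill_slip_angle(make_pitch_plant(a = 0, mu1 = 0.9,
                                                               mu2 = 0.6))), 0)
  p <- make_pitch_plant(mu1 = 0.9, mu2 = 0.6, a = 0.25, h = 0.6, L = 0.5)
  b2 <- downhill_slip_angle(p)
  expect_equal(as.numeric(b2) * 180 / pi, 13.19, tolerance = 1e-2)
  expect_identical(attr(b2, "regime"), "friction-dominated")
})

test_that("stability envelope tabulates the grid and flags failures", {
  rp <- make_roll_plant(); pp <- make_pitch_plant()
  one <- stability_envelope(rp, pp, list(h = pp$h))
  expect_equal(nrow(one), 1)
  expect_equal(one$beta_lim_deg, pitch_limit_angle(pp) * 180 / pi)

  env <- stability_envelope(rp, pp, list(a = c(0.1, 0.2, 0.3),
                                         mu1 = c(0.02, 0.05, 0.08)))
  expect_equal(nrow(env), 9)
  expect_true(all(env$status == "ok"))
  expect_true(all(is.finite(env$beta_lim_deg)))

  # beta_lim non-increasing in h at fixed a
  env_h <- stability_envelope(rp, pp, list(h = c(0.5, 0.7, 0.9)))
  expect_true(all(diff(env_h$beta_lim_deg) < 0))

  # singular points are NaN with a reason, not an abort
  env_bad <- stability_envelope(rp, pp, list(mu1 = c(0.04, 0.5 / (2 * 0.75))))
  expect_true(is.nan(env_bad$beta1_deg[2]))
  expect_match(env_bad$status[2], "singular")
})
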