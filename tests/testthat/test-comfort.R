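# Steady-state gain of the digital weighting chain at one frequency,
# measured on a long sine with the transient discarded.
measured_gain <- function(freq, axis, fs = 1000, dur = 20) {
  sig <- sine_signal(freq, amp = 1, fs = fs, dur = dur, axis = axis)
  w <- apply_frequency_weighting(sig, weighting_spec())
  ch <- w[[paste0("a", axis)]]
  keep <- seq.int(length(ch) %/% 2, length(ch))
  sqrt(mean(ch[keep]^2)) * sqrt(2)
}

test_that("analog weighting gains match the published third-octave table", {
  # frozen table values (gain x 1000 as tabulated with the standard)
  expect_equal(iso_weighting_gain(4, "Wk"), 0.967, tolerance = 0.005)
  expect_equal(iso_weighting_gain(8, "Wk"), 1.036, tolerance = 0.005)
  expect_equal(iso_weighting_gain(0.5, "Wk"), 0.418, tolerance = 0.005)
  expect_equal(iso_weighting_gain(80, "Wk"), 0.132, tolerance = 0.01)
  expect_equal(iso_weighting_gain(1, "Wd"), 1.011, tolerance = 0.005)
  expect_equal(iso_weighting_gain(2, "Wd"), 0.890, tolerance = 0.005)
  expect_equal(iso_weighting_gain(8, "Wd"), 0.253, tolerance = 0.005)
})

test_that("digital weighting reproduces the third-octave gains within 5%", {
  expect_equal(measured_gain(4, "z"), 0.967, tolerance = 0.05)
  expect_equal(measured_gain(8, "z"), 1.036, tolerance = 0.05)
  expect_equal(measured_gain(1, "x"), 1.011, tolerance = 0.05)
  expect_equal(measured_gain(2, "y"), 0.890, tolerance = 0.05)
})

test_that("weighting filters are linear and annihilate the zero signal", {
  zero <- triaxial_signal(numeric(100), numeric(100), numeric(100), 200)
  wz <- apply_frequency_weighting(zero)
  expect_equal(max(abs(c(wz$ax, wz$ay, wz$az))), 0)

  set.seed(5)
  sig <- triaxial_signal(rnorm(400), rnorm(400), rnorm(400), 200)
  tripled <- triaxial_signal(3 * sig$ax, 3 * sig$ay, 3 * sig$az, 200)
  w1 <- apply_frequency_weighting(sig)
  w3 <- apply_frequency_weighting(tripled)
  expect_equal(w3$az, 3 * w1$az, tolerance = 1e-12)
  expect_equal(w3$ax, 3 * w1$ax, tolerance = 1e-12)
})

test_that("weighting rejects unusable sample rates and warns on truncation", {
  slow <- triaxial_signal(numeric(10), numeric(10), numeric(10), 1.5)
  expect_error(apply_frequency_weighting(slow), class = "wheelride_unusable_signal")
  mid <- triaxial_signal(rnorm(100), rnorm(100), rnorm(100), 100)
  expect_warning(apply_frequency_weighting(mid), "truncated")
})

test_that("weighted RMS matches closed forms", {
  fs <- 500
  expect_equal(weighted_rms(rep(-2.5, 1001), fs), 2.5)
  # sine of amplitude A over whole periods -> A/sqrt(2)
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- 1.3 * sin(2 * pi * 2 * t)
  expect_equal(weighted_rms(x, fs, T = 3.5), 1.3 / sqrt(2), tolerance = 1e-6)
  # duplicating a record leaves the RMS unchanged (up to the junction sample)
  expect_equal(weighted_rms(c(x, x), fs), weighted_rms(x, fs), tolerance = 1e-3)
  expect_error(weighted_rms(x, fs, T = 10), class = "wheelride_bad_input")
})

test_that("total vibration combines axes with direction factors", {
  expect_equal(total_vibration(0, 0, 1), 1.0)
  expect_equal(total_vibration(1, 0, 0), 1.4)
  expect_equal(total_vibration(0.1, 0.1, 0.2),
               sqrt(0.0196 + 0.0196 + 0.04), tolerance = 1e-12)
  expect_equal(round(total_vibration(0.1, 0.1, 0.2), 4), 0.2814)
})

test_that("comfort classification resolves the overlapping bands deterministically", {
  expect_equal(classify_comfort(0.1891),
               list(label = "Stay comfortable", C = 1.0))
  expect_equal(classify_comfort(3.0),
               list(label = "Especially uncomfortable", C = 0))
  # overlap region: first matching row in ascending order wins
  expect_equal(classify_comfort(0.9),
               list(label = "Some uncomfortable", C = 0.6))
  expect_equal(classify_comfort(1.3),
               list(label = "Uncomfortable", C = 0.4))
  # half-open intervals: the lower edge belongs to the row
  expect_equal(classify_comfort(0.315)$C, 0.8)
})

test_that("evaluate_comfort composes the pipeline consistently", {
  zero <- triaxial_signal(numeric(400), numeric(400), numeric(400), 200)
  cr <- evaluate_comfort(zero)
  expect_equal(cr$av, 0)
  expect_equal(cr$C, 1.0)

  # identity weighting on a constant 1 m/s^2 vertical signal
  const <- triaxial_signal(numeric(400), numeric(400), rep(1, 400), 200)
  cr2 <- evaluate_comfort(const, weighting_spec("none"))
  expect_equal(cr2$av, 1.0)
  expect_equal(cr2$awz, 1.0)

  # with identity weighting the pipeline equals direct RMS computation
  set.seed(9)
  sig <- triaxial_signal(rnorm(500), rnorm(500), rnorm(500), 200)
  cr3 <- evaluate_comfort(sig, weighting_spec("none"))
  expect_equal(cr3$awx, weighted_rms(sig$ax, 200), tolerance = 1e-12)
  expect_equal(cr3$av, total_vibration(cr3$awx, cr3$awy, cr3$awz), tolerance = 1e-12)
})

test_that("av never decreases when any axis RMS grows", {
  base <- c(0.1, 0.15, 0.2)
  av0 <- total_vibration(base[1], base[2], base[3])
  for (i in 1:3) {
    bumped <- base; bumped[i] <- bumped[i] + 0.05
    expect_gt(total_vibration(bumped[1], bumped[2], bumped[3]), av0)
  }
})

test_that("av is invariant under time reversal of the signal", {
  set.seed(13)
  sig <- triaxial_signal(rnorm(600), rnorm(600), rnorm(600), 200)
  rev_sig <- triaxial_signal(rev(sig$ax), rev(sig$ay), rev(sig$az), 200)
  # identity weighting: exact; spectral weighting preserves magnitude response
  a1 <- evaluate_comfort(sig, weighting_spec("none"))$av
  a2 <- evaluate_comfort(rev_sig, weighting_spec("none"))$av
  expect_equal(a1, a2, tolerance = 1e-12)
  b1 <- evaluate_comfort(sig)$av
  b2 <- evaluate_comfort(rev_sig)$av
  expect_equal(b1, b2, tolerance = 0.05)
})
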