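# Shared plant and signal builders for the suite.

make_roll_plant <- function(...) {
  args <- modifyList(list(Gs = 500, Gu = 150, B = 0.56, m = 0.18, n = 0.28,
                          ks = 15000, kt = 60000, h = 0.75, h1 = 0.35,
                          h3 = 0.15, S1 = 0, S2 = 0, S3 = 0),
                     list(...))
  do.call(roll_plant, args)
}

make_pitch_plant <- function(...) {
  args <- modifyList(list(a = 0.22, h = 0.75, L = 0.5, mu1 = 0.04, mu2 = 0.7),
                     list(...))
  do.call(pitch_plant, args)
}

random_roll_plant <- function() {
  B <- runif(1, 0.4, 0.9)
  h1 <- runif(1, 0.1, 0.4)
  h <- h1 + runif(1, 0.2, 0.6)
  make_roll_plant(Gs = runif(1, 300, 900), Gu = runif(1, 80, 250),
                  B = B, m = runif(1, 0.1, 0.3), n = runif(1, 0.31, 0.45),
                  ks = runif(1, 5e3, 5e4), kt = runif(1, 3e4, 2e5),
                  h = h, h1 = h1, h3 = runif(1, 0.08, 0.25),
                  S1 = runif(1, -0.1, 0.1) * B, S2 = runif(1, -0.1, 0.1) * B,
                  S3 = runif(1, -0.1, 0.1) * B)
}

sine_signal <- function(freq, amp = 1, fs = 1000, dur = 10, axis = "z",
                        location = "chest") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  wave <- amp * sin(2 * pi * freq * t)
  zero <- numeric(length(t))
  triaxial_signal(ax = if (axis == "x") wave else zero,
                  ay = if (axis == "y") wave else zero,
                  az = if (axis == "z") wave else zero,
                  sample_rate = fs, location = location)
}

# Independent truncated-lognormal closed form for the annoyance integral:
# expectation of the clipped log-linear membership under the sensitivity
# lognormal, written directly from normal-distribution identities.
annoyance_closed_form <- function(aw, model) {
  s <- model$sigma
  mu <- log(aw) - s^2 / 2
  z1 <- (log(model$r1) - mu) / s
  z2 <- (log(model$r2) - mu) / s
  ramp <- model$a * (mu * (pnorm(z2) - pnorm(z1)) - s * (dnorm(z2) - dnorm(z1))) +
    model$b * (pnorm(z2) - pnorm(z1))
  ramp + (1 - pnorm(z2))
}
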