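---
title: "Stability and ride-comfort evaluation of the wheelchair-occupant system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability and ride-comfort evaluation of the wheelchair-occupant system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelride)
```

## Scope and model overview

Powered wheelchairs travel slowly (here 0.28 m/s) over pavements with
ditches, curbs and steps. Two distinct questions matter for the occupant:
whether the chair stays upright (quasi-static stability), and how much the
transmitted vibration bothers the occupant (ride comfort). `wheelride`
implements both as small, testable models:

1. **Roll stability.** The chair on a lateral slope is a two-mass system:
   the unsprung mass (wheels, axle) rolls by an angle $\varphi_1$ as the
   tires deflect differentially, and the sprung mass (frame plus occupant)
   rolls by a further $\varphi_2$ about the roll center against the
   suspension's combined roll stiffness $k_r$. The quasi-static rollover
   threshold $\alpha_1$ is the slope at which the upslope tire load $F_1$
   vanishes.
2. **Pitch stability.** At constant, slow speed the suspension barely
   matters in pitch, so the limits are closed forms: the tip-back angle
   $\beta_{\lim} = \arctan(a/h)$ and the uphill/downhill slip angles set by
   the friction coefficients.
3. **Objective comfort.** Triaxial acceleration at the chest and head is
   frequency-weighted (ISO 2631-1 $W_d$ horizontally, $W_k$ vertically),
   reduced to per-axis weighted RMS values $a_{wx}, a_{wy}, a_{wz}$, and
   combined with direction factors $k_x = k_y = 1.4$, $k_z = 1.0$ into the
   total vibration value
   $a_v = \sqrt{k_x^2 a_{wx}^2 + k_y^2 a_{wy}^2 + k_z^2 a_{wz}^2}$, which is
   classified against the seated-comfort band table.
4. **Subjective annoyance.** The population fraction annoyed by a stimulus
   of intensity $a_w$ is modelled as a Fechner log-linear membership
   $v(u) = a\ln u + b$ (0 at the perceptible limit $r_1$, 1 at the tolerance
   limit $r_2$) integrated against a lognormal spread of individual
   sensitivities with mean $a_w$ and coefficient of variation $\delta$:
   $$A(a_w) = \int_{u_{\min}}^{\infty}
     \frac{1}{\sqrt{2\pi}\,u\sigma}
     \exp\!\left(-\frac{(\ln u - \mu)^2}{2\sigma^2}\right) v(u)\,du,
     \qquad \sigma^2 = \ln(1+\delta^2),\; \mu = \ln a_w - \tfrac{\sigma^2}{2}.$$

## The roll moment system and its reconstruction

The quasi-static roll equilibrium couples three statements:

* tire loads under load transfer,
  $F_{1,2} = \tfrac{1}{2}(G_u+G_s)\cos\alpha \mp \tfrac{1}{2}k_t B \varphi_1$,
  which conserve the slope-normal resultant
  $F_1 + F_2 = (G_u+G_s)\cos\alpha$ identically;
* the sprung-body moment about the roll center,
  $k_r \varphi_2 = G_s\left(h\sin\alpha + \cos\alpha\,(S_3 - S_2)\right)$;
* the whole-system moment about the downslope contact line, in which the
  roll angles shift both mass centers downslope and so feed back into the
  balance at first order:
  $\tfrac{1}{2}k_t B^2 \varphi_1 = G h_g \sin\alpha +
  \cos\alpha\,(G_s S_3 + G_u S_1 + G h_g \varphi_1 + G_s h_1 \varphi_2)$,
  with $G = G_s + G_u$ and $h_g = (G_u h_3 + G_s h)/G$.

The symbol pairing deserves a note: in compact write-ups of this system the
roll-center moment is sometimes quoted with the *tire* roll angle on the
suspension side, which cannot be right dimensionally against the tire-load
expression. We assign $\varphi_1$ to the tire-level (unsprung) roll and
$\varphi_2$ to the suspension-level (sprung, relative) roll throughout; with
that assignment the three statements close into a linear system at fixed
$\alpha$, and the retained first-order shift terms are exactly the ones a
small-angle expansion of the rigid geometry produces. Two checks pin the
reconstruction down:

* with offsets zero and growing stiffnesses the rollover limit converges to
  the rigid tipping angle $\arctan\!\big(B/(2h_g)\big)$ (asserted to 0.1° in
  the tests), and any finite compliance lowers the limit below it;
* both moment residuals of the returned solution are below $10^{-10}$ of the
  dominant moment.

`roll_limit_angle()` finds $F_1(\alpha) = 0$ by bracketing on a 256-point
grid over $(0°, 89.9°]$ followed by Brent root-finding to $10^{-10}$ rad.
If tire roll stiffness cannot react the gravity lean moment
($k_t B^2/2 \le G h_g\cos\alpha$) the configuration is statically unstable
and a typed `wheelride_singular_geometry` error is raised rather than a
pseudo-result. The suspension roll stiffness itself comes from the
equivalent-spring construction: one side's springs act through the lever
ratio $m/n$, $k_l = 2k_s(m/n)^2$, and a body roll $d\varphi$ deforms the two
equivalent springs at $\pm B/2$, so $k_r = k_l B^2/2$.

Slip angles are reported as magnitudes. The printed fractions
$\tan\beta_1 = \mu_1(2a-L)/(2h\mu_1-L)$ and
$\tan\beta_2 = (\mu_1-\mu_2)a/((\mu_1-\mu_2)h-L)$ change sign with the
denominator while the physical threshold slope does not carry that sign;
when the tangent is negative the result carries
`regime = "friction-dominated"` so the caller can see which branch applied.
Singular denominators ($2h\mu_1 = L$, $(\mu_1-\mu_2)h = L$) raise typed
errors instead of returning $\pm\pi/2$.

## Frequency weighting: realization and verification

$W_k$ and $W_d$ are implemented as the standard analog cascade —
band-limiting two-pole high/low pass at 0.4/100 Hz ($Q = 1/\sqrt2$), an
acceleration-velocity transition (corner 12.5 Hz for $W_k$, 2 Hz for
$W_d$, $Q = 0.63$), and for $W_k$ an upward-step section (2.37/3.35 Hz,
$Q = 0.91$) with no DC renormalization — and discretized per second-order
section by the bilinear transform, each section prewarped at its own corner
frequency. Verification is against the published third-octave gain table
(e.g. $|W_k| = 0.967$ at 4 Hz, $1.036$ at 8 Hz; $|W_d| = 1.011$ at 1 Hz,
$0.890$ at 2 Hz), not against stored digital coefficients, both for the
analog magnitude (to 0.5%) and for the digital chain measured on long sine
inputs (to 5%, the tolerance the third-octave tabulation itself supports).

Numerical notes: a section corner at or above Nyquist (the 100 Hz
band-limit pole when sampling at 200 Hz) cannot be prewarped; the transform
falls back to the plain bilinear map and the section degenerates gracefully
towards an all-pass, which truncates the weighting only where its gain is
already below 0.15. Records are required to be uniformly sampled;
`validate_signal()` rejects time bases whose step jitter reaches 1% of the
nominal step rather than interpolating over what are almost certainly
dropped samples. The RMS integral is trapezoidal on the sample grid over a
window `[0, T)` (default: the full record); no detrending is applied unless
requested, since a static gravity offset is a real part of the vertical
channel unless the sensor frame already removes it.

Because published total-vibration tables do not always state whether
spectral weighting was applied on top of the direction factors,
`weighting_spec("none")` provides an identity-weighting path; the default
is the full ISO weighting.

The comfort band table overlaps by construction (0.5–1.0 sits inside
0.315–0.63's successor, and so on, as in the source guidance).
`classify_comfort()` therefore applies a deterministic precedence: first
matching row in ascending order, on half-open intervals $[\ell, u)$. An
$a_v$ of 0.9 m/s² classifies as "Some uncomfortable" ($C = 0.6$), not
"Uncomfortable", under this rule.

## Annoyance model: parameters and numerical choices

Defaults are the seated-body limits $r_1 = 0.315$, $r_2 = 2.5$ m/s² and
$\delta = 0.3$, the midpoint of the 0.2–0.5 range quoted in the
psychophysics literature. The lower integration limit is $u_{\min} = r_1$:
below the perceptible limit the membership is identically zero, so the
choice costs nothing and anchors the integral at a physically meaningful
point.

Solving the calibration system at the default limits gives
$a = 1/\ln(r_2/r_1) = 0.4827$, $b = -a\ln r_1 = 0.5577$. These coefficients
are quoted — and used — in the ride-comfort literature at two decimals,
$a = 0.48$, $b = 0.56$, and the published annoyance percentages for this
system are only reproduced at that precision (the exact coefficients give
3.31% where 3.48% is published). `annoyance_model()` therefore rounds the
calibrated coefficients to `coef_digits = 2` by default; passing
`coef_digits = NULL` gives the exact calibration, for which $v(r_1) = 0$ and
$v(r_2) = 1$ hold to machine precision. The membership is hard-clipped:
$v \equiv 0$ below $r_1$ and $v \equiv 1$ above $r_2$, never the
extrapolated $a\ln u + b > 1$.

The integral is evaluated by splitting at $r_2$: adaptive quadrature
(rel. tol. $10^{-10}$) on $[u_{\min}, r_2]$, where the integrand is smooth,
plus the exact lognormal survival mass above $r_2$, where $v \equiv 1$ — so
no truncation of the upper tail is needed at all. The tests compare this
against an independently derived truncated-lognormal closed form over
$a_w \in [0.05, 5]$ and $\delta \in \{0.2, 0.3, 0.5\}$ at $10^{-6}$
absolute. One consequence worth knowing: $A(r_1) \approx 4.9\%$, not zero —
half of the sensitivity distribution lies above its mean, so a
perceptible-limit stimulus already annoys a few percent of the population.

## What the synthetic generator emulates — and what it does not

No measured traversal records are distributed with the package, so the
generator produces surrogates with the study's geometry and kinematics: the
ditch pavement (2.5 m approach, 100 mm × 50 mm ditch, 1.4 m run-out), the
step pavement (1.4 m approach, 40 mm rise, 0.7 m plateau, 30 mm drop, 2.0 m
run-out), constant 0.28 m/s travel, and one excitation event per axle per
obstacle with the rear axle lagging by `wheelbase/speed`. Each event
excites a damped sinusoid whose first lobe is a half-sine of 0.35 s
(roughly the contact length over the travel speed) with damping ratio 0.3 —
the simplest event-localized transient; over 80% of the signal variance
stays within ±1 s of the event times. Vertical response dominates; the
fore-aft (pitch) channel is scaled per location, with the head gain 1.5×
the chest gain, encoding the qualitative observation that the
loosely-supported head swings harder than the chest; the lateral channel is
low-level. A Gaussian noise floor of 0.02 m/s² RMS per axis stands in for
sensor noise. The wheelbase default of 0.5 m is an illustrative value for a
compact powered wheelchair, as is everything in the example plant configs —
the study platform's numeric plant parameters are not published, so the
configs ship clearly labelled as illustrative defaults.

Amplitude is the one quantity the surrogate cannot derive from geometry, so
it is calibrated: `calibrate_to_target()` rescales a generated record so
the evaluated $a_v$ equals a published total-vibration value exactly (the
pipeline is homogeneous of degree one in the signal, so the factor is just
the ratio). Passing tests on these surrogates demonstrates that the
evaluation chain — weighting, RMS, direction factors, classification,
annoyance — reproduces the published table values from signals with the
right energy, localization and ordering; it does **not** validate waveform
shape, spectral content beyond the pulse model, or any multibody dynamics
of a real chair, none of which the surrogate attempts.

All generation is seeded (R's Mersenne Twister, seed offset per
measurement location) and restores the caller's RNG state; identical
scenarios and seeds give bit-identical records and byte-identical report
files.

## Problem sizes and determinism in the shipped checks

The test-suite and the reproduction script run the full chain at the study
geometry: roughly 18 s of signal at 200 Hz (about 3 600 samples per
location), 200 randomized plants for the load-conservation property, and
41-point intensity grids for the quadrature/closed-form comparison —
seconds of compute in total. The annoyance values reported by the
reproduction script depend on the seed only through the synthetic-signal
route, and the calibration step makes that route exact, which is why
different seeds agree to 12 significant digits.

## Known limitations

* The stability model is quasi-static; transient rollover (obstacle impact
  while on a slope) and cornering dynamics are out of scope, as is any
  steering condition.
* Angular vibration and the foot contact point are ignored in the comfort
  model; only chest/head/frame linear vibration is evaluated.
* The anthropometric module ships the published 18-segment table as-is: the
  segment masses sum to 59.555 kg although the nominal subject is 65 kg,
  and the dimension list carries two distinct "Ankle circumference" values.
  Both quirks are preserved (and asserted) rather than reconciled, since
  regenerating them would require regression coefficient sets that are not
  published.
* The regression evaluator `gebod_regression()` takes caller-supplied
  coefficients for the same reason: inventing coefficient sets would
  fabricate data.
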