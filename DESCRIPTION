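Package: wheelride
Title: Stability and Ride-Comfort Analysis of the Wheelchair-Occupant System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static stability limits and whole-body-vibration comfort
    evaluation for a powered wheelchair carrying a seated occupant. Provides
    closed-form and numerical rollover, pitch and slip stability limits from
    a small set of plant parameters (masses, track, suspension and tire
    stiffnesses, friction); ISO 2631-1 frequency-weighted RMS acceleration and
    total-vibration comfort classification for triaxial acceleration records;
    a psychophysical annoyance-rate model combining a Fechner log-linear
    membership function with a lognormal inter-individual sensitivity
    distribution; anthropometric body-segment fixtures; and a seeded synthetic
    signal generator emulating ditch and step obstacle traversal so the full
    pipeline is testable without instrumented trials.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
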