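Package: hydrokin
Title: Release Kinetics and Pattern Dynamics for Hydrogel Drug-Delivery Films
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of cumulative drug-release curves from thin hydrogel
    films. Fits the burst-release phase with the Higuchi square-root law
    (constrained through the origin), converts the Higuchi constant to a
    diffusion coefficient via the film-thickness relation kH = 2*sqrt(D)/d,
    and models long-time release with a truncated complementary-error-function
    series solution of slab diffusion. Also provides complex-amplitude
    release-pattern dynamics (SL(2,R) Moebius action, harmonic-map amplitudes,
    amplitude maps, time traces, delay-embedding attractor reconstruction) and
    a seeded synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
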