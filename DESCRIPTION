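Package: dashsim
Title: Simulation of Dynamic Adaptive Scattering Compensation Holography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained numerical testbed for indirect wavefront
    sensing in two-photon excited fluorescence (TPEF) microscopy through
    turbid media. Implements the DASH algorithm, in which every phase-
    stepping interferometric mode measurement immediately updates a
    holographic correction field on the spatial light modulator, together
    with reference implementations of F-SHARP, IMPACT, the continuous
    sequential algorithm, the partitioning algorithm, and a genetic
    algorithm. A Fourier-optics forward model (phase-only pupil scatterer,
    unitary propagation, |E|^4 layer response, Poisson photon counting)
    supports seeded convergence benchmarks with enhancement traces,
    standard-error bands, and measurement and photon-budget bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
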