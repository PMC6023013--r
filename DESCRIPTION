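Package: ctcchip
Title: Simulation of an Integrated Microfluidic Biochip for Magnetophoretic
    CTC Separation and Electroosmotic Mixing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-dimensional multiphysics simulation of a microfluidic
    platform that immunomagnetically separates magnetically tagged
    circulating tumor cells (CTCs) in a diverging channel beneath a
    permanent magnet, then mixes the CTC-enriched stream with lysis buffer
    by AC electroosmosis. Provides a structured-grid incompressible flow
    solver (Stokes and steady Navier-Stokes), an analytic magnetostatic
    field of a uniformly magnetized rectangular magnet with a numeric
    scalar-potential cross-check, Lagrangian particle tracing with
    Schiller-Naumann drag and magnetophoretic forcing, Helmholtz-Smoluchowski
    slip-driven electrokinetic mixing with a coefficient-of-variation mixing
    index, and orchestrated parametric studies (magnet position, ancillary
    flow, drive voltage and frequency, grid convergence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
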