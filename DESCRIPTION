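Package: braggfxs
Title: Bragg Peak Intensity Recovery from Fluctuation X-Ray Scattering
    Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for crystallographic fluctuation X-ray scattering (FXS)
    analysis: angular intensity correlation functions of Bragg peak lists,
    spherical-harmonic decomposition of reciprocal-space intensity volumes
    on the Driscoll-Healy grid, harmonic order matrices extracted from
    correlation volumes by Legendre pseudo-inversion, and an iterative
    projection algorithm (error reduction and hybrid input-output) that
    recovers Bragg peak intensities from a measured correlation function
    using a modulus constraint built from the harmonic order matrices and
    a sparse support constraint built from known unit-cell parameters.
    Includes unit-cell geometry and reciprocal-lattice enumeration, a toy
    structure-factor generator for synthetic test crystals, and the
    crystallographic quality metrics (R factor, R_iso, mean atomic
    displacement) used to assess recoveries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
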