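Package: spidr
Title: Weak-Form Sparse Discovery of Governing Equations for Active Nematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data-driven identification of parsimonious governing equations
    for two-dimensional active nematic films, such as kinesin-driven
    microtubule suspensions at an oil-water interface.  Builds
    symmetry-constrained libraries of symbolic tensor terms from director and
    velocity fields, evaluates them in weak form against smooth compactly
    supported weight functions over randomly placed spatiotemporal
    subdomains, and selects sparse relations by sequentially thresholded
    regression on the minimum-singular-vector solution of the resulting
    homogeneous linear system.  Includes field preprocessing (moving
    least-squares smoothing, nondimensionalization, reliability masking,
    structure-tensor director extraction), synthetic field generators with
    planted dynamics for validation, coefficient uncertainty quantification
    by half-sample resampling, and strong-form diagnostic maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
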