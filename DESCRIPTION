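Package: popwave
Title: Travelling-Wave Analysis of Cyclic Population Growth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting and characterising periodic travelling
    waves in spatio-temporal population survey data. Transect-level
    abundance surveys are aggregated into centroid-by-quarter growth rates,
    which are modelled as penalized-spline functions of space-modified time
    under a catalogue of twelve wave hypotheses (null, planar, radial
    expanding or contracting, river-split and dual additive forms). Wave
    parameters (directions, epicentres, speeds) are estimated by a direct
    grid search followed by simulated annealing around a weighted GAM inner
    fit, models are compared by an adjusted AIC that charges for the wave
    parameters, and profile confidence intervals are computed by
    likelihood profiling. A synthetic-data module simulates surveys over
    known wave fields, including an adaptive monitoring design, so the
    whole pipeline can be validated by parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
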