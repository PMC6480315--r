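Package: oceancdom
Title: Ocean-Color Retrievals of CDOM Absorption, Spectral Slope, and
    Dissolved Organic Carbon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for global ocean-carbon retrievals from ocean color.
    Fits the exponential model of chromophoric dissolved organic matter (CDOM)
    absorption over the spectral-slope windows in common use, applies published
    multiple-linear-regression (MLR) retrievals of CDOM absorption, CDOM
    spectral slope, and dissolved organic carbon (DOC) from remote-sensing
    reflectance and salinity, partitions combined dissolved-plus-detrital
    absorption from semi-analytical inversions, implements the record-level and
    population quality-control and match-up rules used to assemble global
    bio-optical algorithm databases, provides the model-skill metric suite
    behind Taylor and target diagrams, and supplies monthly anomaly and
    climate-index correlation operators.  Seeded synthetic-fixture generators
    emulate every input class so the whole toolkit is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
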