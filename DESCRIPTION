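Package: woodsucc
Title: Succession Analysis for Insect Communities on Dead Wood
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing early succession of insect communities on
    ephemeral dead-wood resources sampled repeatedly at fixed traps. Computes
    permanent species gain and loss rates (colonization and extinction rates
    normalised by mean interval richness), fits negative-binomial and Gaussian
    mixed trajectory models with time-by-environment structure, performs
    Hellinger-transformed partial redundancy analysis with Freedman-Lane
    permutation tests and type-II scaled ordination scores, partitions
    community variance among predictor sets via adjusted R-squared
    inclusion-exclusion, and simulates study-shaped colonization-extinction
    data with known ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    multcomp,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
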