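Package: leafheat
Title: Thermal Acclimation Analysis for Urban Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing thermal acclimation of trees growing in
    contrasting urban microclimates (urban heat island versus cooler
    sites). Implements a linearized leaf-scale energy-balance model for
    sun-leaf temperature, Gaussian photosynthesis-temperature response
    fitting (optimal temperature, optimal assimilation, curve width),
    logistic chlorophyll-fluorescence heat-tolerance estimation (Tcrit,
    T50, T95) with bootstrap confidence intervals, thermoregulatory leaf
    trait computation including effective leaf width from silhouettes,
    and paired-site microclimate contrasts on serially correlated
    temperature series. A seeded synthetic-data generator emulating the
    nested study design (species by site by tree) makes the full
    pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
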