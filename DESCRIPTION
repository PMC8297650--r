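Package: uvcanopy
Title: UV-B Radiation Interception and Bioactive Compound Yields in 3D Rosette Canopies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Monte Carlo ray tracing of PAR and UV radiation interception in
    three-dimensional rosette canopies under LED arrays, UV-B dosimetry with
    biological weighting by a generalized plant action spectrum, and regression
    of bioactive-compound responses (total phenolics, total flavonoids, radical
    scavenging activity) on cumulative absorbed UV energy to estimate UV energy
    yields by leaf position and growth stage. Includes a synthetic rosette
    generator (spiral phyllotaxis), a plant-factory scene builder with
    Lambertian LED bar sources, per-leaf absorbed-flux tallies with Monte Carlo
    standard errors, and an end-to-end deterministic pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
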