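Package: spotbias
Title: Diffusion-Limited Hybridization Kinetics and Spot-Position Bias in
    DNA Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and quantifies the systematic boundary bias in static DNA
    microarray hybridizations caused by position-dependent lateral diffusion
    of target molecules. Provides a dimensionless scaling analysis (a
    Damkohler-type parameter comparing hybridization and diffusion
    timescales) that justifies treating probe spots as perfect sinks, a 3D
    unsteady Fickian diffusion solver with absorbing spot disks and no-flux
    chamber walls that computes per-spot target flux over the hybridization
    time, ring-position bookkeeping and transect definitions for square spot
    blocks, position-wise bias statistics for one- and two-colour intensity
    tables (normalized ring profiles, inner/outer ratios, channel ratios,
    position t-tests), a synthetic array-data generator with
    boundary-enhanced ring profiles and replicate hybridizations, and
    readers/writers for a minimal GenePix-results-style dialect and CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'geometry.R'
    'bias.R'
    'io.R'
    'scaling.R'
    'solver.R'
    'synthetic.R'
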