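Package: kinshrink
Title: Shrinkage Estimation of the Realized Relationship Matrix and GBLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Marker-based estimation of the additive (realized) relationship
    matrix for inbred and outbred populations, scaled so the mean diagonal
    element equals one plus the population inbreeding coefficient. Includes a
    shrinkage estimator of the underlying genomic covariance matrix with an
    analytically optimal (mean-squared-error minimizing) intensity for
    low-density marker panels, marker-based inbreeding coefficients at the
    locus, individual and population level, GBLUP breeding-value prediction
    with REML variance components via eigendecomposition, and a population
    and trait simulator for benchmarking shrinkage against marker density,
    population structure and heritability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'genotype-io.R'
    'kinship.R'
    'shrinkage.R'
    'inbreeding.R'
    'gblup.R'
    'simulate.R'
    'experiments.R'
    'cli.R'
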