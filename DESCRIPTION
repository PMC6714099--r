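Package: mutorsim
Title: Individual-Based Simulation of Mutation-Rate Evolution Under
    Directional Environmental Change
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time, individual-based simulator of a panmictic
    diploid sexual population carrying an evolving mutator locus and a
    single additive adaptation locus. The environmental optimum follows a
    directional trend with variance-normalized AR(1) colored noise
    (blue, white or red). Fitness is Gaussian stabilizing selection
    around the realized optimum; fecundity is density dependent with
    lottery-polygyny mating and Poisson offspring numbers. The
    distribution of mutation fitness effects is a quantile-shifted
    normal so that a controlled fraction of new mutations is beneficial.
    Includes a scenario-grid experiment runner with seeded replicates,
    extinction bookkeeping, CSV/JSON output and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
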