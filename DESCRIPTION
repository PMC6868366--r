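Package: pathsampler
Title: Transition Path and Interface Sampling for Base-Pair Flipping Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Flexible-length one-way-shooting transition path sampling (TPS)
    and transition interface sampling (TIS) engines for rare-event kinetics,
    exercised on a two-dimensional, two-channel Langevin model of the
    Watson-Crick to Hoogsteen base-pair transition. Includes the geometric
    order parameters used to follow base flipping in duplex DNA (hydrogen-bond
    distances, the arctan2 progress coordinate, glycosidic and base opening and
    rolling angles, hydration counts), inside/outside transition-channel
    classification with a Bayesian channel-preference analysis, WHAM
    combination of interface crossing histograms, and rate-constant and
    free-energy arithmetic, together with a brute-force rate oracle for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    zoo
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
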