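Package: matesim
Title: Agent-Based Simulation of Sexual Selection Under Disrupted Mating Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based model of good-genes inter-sexual selection in a
    guppy-like life history with overlapping generations. A diploid viability
    gene confers a survival advantage, males advertise their viability through
    a signal trait, and females carry a heritable mating-preference threshold.
    An environmental parameter (representing, for example, endocrine-disrupting
    chemicals) can degrade the honesty of the male signal for a scheduled
    period. The package provides the per-step demographic engine (density
    dependent juvenile mortality, senescent adult mortality, Mendelian
    inheritance with mutation, threshold mate choice), time-point observers of
    allelic means, and an experiment harness for seeded replicate runs,
    disruption parameter sweeps, calibration correlations and extinction
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
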