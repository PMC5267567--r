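Package: ssdallometry
Title: Allometry of Sexual Size Dimorphism with Traditional and
    Phylogenetic Comparative Methods
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests Rensch's rule (positive allometry of sexual size
    dimorphism) in comparative body-size datasets, with turtles as the
    motivating system. Provides the Lovich-Gibbons dimorphism index and
    direction censuses, standardized major-axis (SMA) regression of log
    male on log female size with confidence-interval based verdicts
    (Rensch's rule, its converse, or isometry), Felsenstein phylogenetic
    independent contrasts with through-origin SMA, Blomberg's K with a
    permutation test, sex-specific mass-length regressions compared by a
    Chow test, and a synthetic-data generator (pure-birth trees, Brownian
    trait evolution, multi-population sampling, cubic mass-length
    scaling) so every stage of the pipeline can be validated by
    parameter recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
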