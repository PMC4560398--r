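Package: swarmlead
Title: Leadership Emergence in Evolved Groups of Foraging Robots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulator of a group of four sensor-equipped
    differential-drive robots that must forage collectively in a square
    arena with two food zones. Feed-forward neural controllers encoded
    as bit strings are evolved with a heterogeneous genetic algorithm
    in which each robot role has its own separately ranked population.
    The package also provides the quantitative battery used to study
    leader emergence: barycenter-based leadership detection, individual
    and collective fitness indicators, follower capability, leader
    mobility and vision, robot-removal perturbation tests, temporal
    curve analysis with super-smoothing and derivatives, and a
    leadership-style classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
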