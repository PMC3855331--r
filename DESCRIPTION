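Package: rgtraits
Title: Trait-Modulated Reinforcement Learning for the Rat Gambling Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and estimation toolkit for a temporal-difference
    learning model of the Rat Gambling Task (RGT) in which three stable
    behavioural traits modulate learning: reward seeking (a multiplicative
    weight on delivered rewards), risk seeking (an additive bonus
    proportional to the running spread of experienced penalties), and
    cognitive inflexibility (an exponentially decaying learning rate).
    Provides the task environment with probabilistic time-out penalties and
    its spatially reversed variant, fast seeded session simulation,
    simulation-based maximum-likelihood estimation of per-individual trait
    parameters from binned performance profiles, nested model comparison
    (likelihood-ratio test, BIC), Monte-Carlo permutation correlation tests,
    median-split trait profiling, sum-of-ranks composite indices, and a
    synthetic-cohort generator with known ground truth for parameter-recovery
    studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
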