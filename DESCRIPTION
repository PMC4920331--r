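Package: fbdage
Title: Bayesian Phylogenetic Estimation of Fossil Ages Under the
    Fossilized Birth-Death Process
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the ages of fossil taxa from discrete morphological
    characters by Bayesian tip dating under the fossilized birth-death
    (FBD) tree prior and the Lewis-Mk model of morphological evolution.
    Provides the analytic density of fossil sampling times under the FBD
    process (Kendall birth-death transition probabilities, a closed-form
    summation, and implicit prior constructions on the origin time and
    fossil sampling proportion), a forward simulator of sampled-ancestor
    trees and character matrices, a Metropolis-Hastings sampler over
    fossil ages, divergence times, clock and FBD parameters at fixed
    topology, and Bayes-factor tests of stratigraphic age ranges with the
    associated summary statistics (HPD intervals, effective sample sizes,
    error and precision metrics).
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
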