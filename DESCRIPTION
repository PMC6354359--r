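Package: fishkin
Title: Kin Structure, Cuckoldry, and Inclusive Fitness in Socially
    Monogamous Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing relatedness structure among socially
    paired males, females, and extra-pair (cuckolder) males in socially
    monogamous species genotyped at codominant markers such as
    microsatellites. Implements symmetric pairwise relatedness
    estimators (Queller-Goodnight and Lynch-Ritland), reconstruction of
    cuckolder multilocus genotypes from mothers and extra-pair full-sib
    groups, season-stratified randomization tests for elevated
    relatedness (mean, variance, skewness) with Benjamini-Hochberg
    control, intercept tests for deviations of parent-offspring
    relatedness from pedigree expectation, spatial kin-structure tests
    (a radius-sweep difference-of-maxima statistic and Mantel tests),
    and an inclusive-fitness game-theoretic model of cuckoldry
    tolerance built on Skellam-distributed sperm competition. A
    synthetic-data generator produces genotypes, broods, and territory
    maps with known pedigree structure so the whole pipeline can be
    exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    lme4,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
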