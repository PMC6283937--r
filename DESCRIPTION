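Package: nicheBreadth
Title: Realized and Fundamental Niche-Breadth Analysis for Sexual-Asexual
    Species Pairs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies ecological niche breadth of herbivorous insect
    populations and species from host-plant occurrence counts (realized
    niche) and feeding-trial performance (fundamental niche) using the
    inversed Tau specialization index, together with Gini-Simpson colour
    polymorphism diversity, percentile-bootstrap confidence intervals,
    permutation comparisons between paired sexual and asexual lineages,
    phylogenetic generalized least squares under Brownian motion, and
    binomial GLM / ANOVA interaction tests for designed feeding
    experiments. Includes a synthetic-data generator with known ground
    truth (multinomial host use, frozen-niche-variation and
    general-purpose-genotype scenario presets, Brownian tip traits) for
    calibration and recovery testing, and pipeline drivers that write
    tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    vegan,
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'tau.R'
    'simpson.R'
    'bootstrap.R'
    'pgls.R'
    'trials.R'
    'synthetic.R'
    'pipeline.R'
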