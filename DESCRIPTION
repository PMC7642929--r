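Package: sarnam
Title: Shade-Avoidance Plasticity QTL Mapping and Path Analysis in NAM Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of phenotypic
    plasticity in nested association mapping (NAM) populations of recombinant
    inbred lines. Provides a synthetic NAM generator with known ground truth
    (recombination under the Haldane map function at the selfed-RIL limit,
    cascading developmental traits in sun and shade), mixed-model estimation
    of per-line genotype and genotype-by-environment effects with variance
    components, PVE and the coefficient of genetic variation in plasticity,
    joint multi-family forward-stepwise QTL mapping by Haley-Knott regression
    with background-kinship correction and permutation-based genome-wide
    thresholds, TASSEL-style QTL confidence intervals, and QTL-path/mediation
    analysis that separates direct from developmentally transmitted QTL
    effects in each light environment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
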