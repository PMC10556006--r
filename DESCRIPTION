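Package: mgmgrowth
Title: Maintenance-Growth Model for Ontogenetic Growth of Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inverse-method fitting of the Maintenance-Growth
    Model (MGM), an energy-balance model of individual ontogenetic growth in
    which growth is the net outcome of assimilation and metabolic costs for
    maintenance, feeding and tissue synthesis. Maintenance is split into a
    non-negotiable (basal) part and a negotiable (defence) part that can be
    downregulated under food restriction, which permits hyperallometric
    maintenance scaling and near-symmetric hump-shaped growth-rate curves of
    the kind observed in house crickets. Provides the component energy-budget
    functions, the growth ODE and its von Bertalanffy-type simplifications,
    comparator growth models (generalized supply-minus-expenditure power laws
    and the logistic), least-squares parameter estimation with a
    root-sum-of-squares goodness-of-fit score, food-restriction scenario
    sweeps, a cohort-data reduction pipeline (averaging, difference-ratio
    growth rates, quadratic smoothing) and a seeded generator of synthetic
    cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
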