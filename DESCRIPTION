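Package: sorbfate
Title: Biochar Micropollutant Sorption Screening and Sand-Filter Transport
    Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating biochar sorbents for the removal of
    organic micropollutants (antibiotics, pesticides, pharmaceuticals)
    from water. Implements mass-balance computation of single-point
    sorption coefficients from batch equilibrium experiments, multi-model
    adsorption isotherm fitting (linear, Freundlich, Langmuir, BET) with
    eligibility screening and multilayer-sorption flagging, hierarchical
    clustering of sorption-coefficient profiles across sorbents and
    compounds, finite-volume simulation of one-dimensional
    sorption-retarded solute transport through layered sand-biochar
    filter columns (local-equilibrium and first-order kinetic sorption
    variants) with closed-form verification solutions, inverse estimation
    of partitioning coefficients from breakthrough curves, comparison of
    batch-derived and field-fitted sorption coefficients with censored
    value handling, and seeded synthetic-data generators emulating the
    batch and pilot filtration designs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    minpack.lm,
    pracma,
    ape,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
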