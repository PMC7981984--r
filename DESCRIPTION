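Package: nestMCA
Title: Equivalent Kinetic Model Populations over Nested Metabolic Network
    Reductions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs populations of kinetic metabolic models that remain
    equivalent across nested reduced stoichiometric networks.  Implements
    thermodynamics-based flux analysis (TFA) with an away-from-equilibrium
    displacement constraint, thermodynamic variability analysis, hit-and-run
    sampling of flux and log-concentration polytopes with PCA-based selection
    of a representative steady state, a mixed-integer program that transfers a
    reference steady state from a smaller model into a larger nested model
    with a minimum number of band violations, ORACLE-style uniform sampling of
    enzyme saturation states with stratified resampling across model levels,
    metabolic control analysis (flux and concentration control coefficients
    with summation-theorem verification), and a deviation index quantifying
    how flux-control conclusions change with network complexity.  A synthetic
    generator produces nested toy model families so the whole workflow runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
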