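Package: hetflux
Title: Steady-State 13C Metabolic Flux Analysis for Heterogeneous Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting pipeline for steady-state 13C metabolic flux
    analysis (MFA), built to study how cell-type heterogeneity confounds flux
    estimation from averaged labelling data. Provides an atom-transition network
    format and parser, free-flux parameterization of the stoichiometric null
    space, elementary-metabolite-unit (EMU) label simulation with a brute-force
    isotopomer oracle, GC-MS mass-isotopomer processing (natural-abundance
    correction for tBDMS-derivatized amino acid fragments, fractional
    enrichment, ion-count quality control), weighted least-squares flux fitting
    with Monte Carlo replicates and parameter-continuation confidence
    intervals, mixture-of-cell-types experiments with physiology summaries, and
    synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
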