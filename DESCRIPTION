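Package: chelatherm
Title: Thermodynamic Characterization of Metal-Chelator Complexes from
    NMR, ITC and Time-Resolved Luminescence Titrations
Version: 0.1.0
Authors@R:
    person("chelatherm", "developers", email = "chelatherm@example.org",
           role = c("aut", "cre"))
Description: An inference chain for the solution thermodynamics of metal
    complexes with polyprotic macrocyclic chelators such as macropa.
    Determines ligand pKa ladders from pD-dependent NMR chemical-shift
    titrations with sigmoidal (bi)dose-response fits and deuterium
    correction; solves mass-action speciation of protolytic ligands plus
    M_mL_l complexes at fixed pH (binding polynomials, conditional
    stability constants); forward-models and globally fits isothermal
    titration calorimetry (ITC) injection heats on a speciation basis
    with displaced-volume corrections to extract log K, reaction
    enthalpies and active fractions; decomposes time-resolved
    laser-induced fluorescence (TRLFS) titration cubes by trilinear
    alternating least squares with exponential-decay and
    speciation-linked constraints; estimates Eu(III) hydration numbers
    from luminescence lifetimes via the Horrocks relation; and quantifies
    parameter uncertainty throughout by seeded Monte Carlo refitting.
    Includes seeded synthetic-data generators for every stage and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
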