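Package: kowtherm
Title: Thermodynamic and NMR Exchange Analysis of Fold-Switching KOW Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium-unfolding and chemical-exchange analysis for small
    beta-barrel (KOW) domains, including the fold-switching RfaH C-terminal
    domain. Implements two-state thermal and chemical (linear extrapolation
    method) unfolding fits of spectroscopic melts, a differential scanning
    calorimetry partition-function model with a temperature-dependent heat
    capacity change, two-state Bloch-McConnell simulation and per-residue or
    global fitting of chemical exchange saturation transfer (CEST) profiles
    with conversion of exchange parameters to rates, lifetimes and Gibbs
    energies, secondary chemical-shift and through-hydrogen-bond scalar
    coupling analyses, and seeded synthetic-data generators for all four
    measurement types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Matrix,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Biostrings,
    optparse
Config/testthat/edition: 3
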