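Package: sulfidogen
Title: Sulfide Production Kinetics, Thermodynamics and Remediation Dosing
    for Acidic Pit Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing microcosm experiments that stimulate
    dissimilatory sulfate reduction in acidic pit-lake water with organic
    substrates: zero-order sulfide production kinetics under a
    rate-threshold window rule (lag time, rate, maximum sulfide, per-COD
    efficiency, per-gram yield, metal removal times); balanced
    substrate-oxidation/sulfate-reduction reactions with standard and
    condition-adjusted Gibbs free energies per mole of substrate carbon;
    Henderson-Hasselbalch and buffer-capacity calculations for volatile
    fatty acid mixtures with a charge-balance pH solver; exact
    small-sample Mann-Whitney U and Kendall tau tests; a whole-lake
    metal-sulfide precipitation dosing calculator; and a seeded
    synthetic-data generator producing replicate microcosm time series
    with lag/zero-order/plateau structure, stoichiometric metal
    depletion and coupled VFA/pH trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
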