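Package: s9conf
Title: Conformational State and Interface Analysis of S9-Family Oligopeptidases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative structural analysis of two-domain S9-family
    peptidases such as oligopeptidase B (OpB). Measures catalytic-triad
    (Ser/His/Asp) geometry and interdomain center-of-mass separation, computes
    solvent-accessible and buried surface areas with a deterministic
    Shrake-Rupley implementation, censuses interdomain hydrogen bonds and salt
    bridges, and combines these metrics into closed/intermediate/open
    conformational-state calls and a two-way classification of the D-loop
    stabilization mode (interdomain salt bridge versus complementary charged
    surfaces).  Also classifies OpB sequences into SpOpB-like and TbOpB-like
    groups from alignment-anchored residue positions, aggregates group
    frequencies by taxonomy, and fits Kitz-Wilson irreversible-inhibition
    kinetics (pseudo-first-order inactivation constants, K_i and k_2).
    Seeded synthetic generators produce toy structures, sequence sets and
    inactivation curves with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
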