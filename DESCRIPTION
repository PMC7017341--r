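Package: flagbalance
Title: Balance-Point Modelling and IFT Quantification for Flagellar Length Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing flagellar length control in Chlamydomonas
    through intraflagellar transport (IFT). Implements the balance-point
    differential equation for flagellar length (length-dependent assembly
    balanced against length-independent disassembly), its steady state and
    mutant length-ratio predictions; an automated kymograph quantifier that
    recovers IFT train speed, injection frequency and train magnitude by
    projection-contrast maximisation; log-log power-law fits of IFT
    injection rate against flagellar length with per-strain fold-change
    summaries; and a binomial null model for cargo occupancy of IFT trains.
    Seeded synthetic-data generators emulate every input class (kymographs,
    injection-scaling tables, occupancy tables) with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
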