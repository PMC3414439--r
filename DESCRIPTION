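Package: comboscreen
Title: Signature-Based Screening and Synergy Assessment of Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Matches disease gene-expression signatures, restricted to
    hypergeometrically enriched signaling pathways, against a compendium of
    rank-ordered drug-treatment expression profiles using unweighted
    Kolmogorov-Smirnov enrichment statistics. Scores single molecules and
    molecule pairs (the profiles of two molecules pooled as one set) per
    pathway with subset-permutation significance, and ranks candidates by
    counting pathways whose set-level score crosses fixed thresholds.
    Includes median-effect (Chou-Talalay) dose-response modelling with
    combination-index and dose-reduction-index computation for validating
    predicted pairs, and seed-deterministic synthetic-data generators for
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
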