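Package: qpopr
Title: Quadratic Phenotypic Optimization for Drug and Splice-Switching
    Oligonucleotide Combination Screens
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for small-run combinatorial viability screens against a
    panel of dose-titratable modulators (small molecules and splice-switching
    oligonucleotides). Constructs orthogonal array composite designs (a
    two-level fractional factorial merged with a three-level orthogonal
    array), fits second-order response-surface models of viability with
    bidirectional stepwise term selection and extra-sum-of-squares F tests,
    exhaustively projects and ranks all dose combinations, summarizes pairwise
    efficacy as response-surface grids and polygonogram percentile bins, and
    quantifies drug-pair synergy by the Chou-Talalay median-effect method
    (combination and dose-reduction indices) and Bliss independence. Seeded
    synthetic-data generators emulate screens and dose-response curves with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
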