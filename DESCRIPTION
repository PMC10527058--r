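Package: specuniq
Title: Differential Spectral-Count Proteomics with Presence/Absence Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A label-free spectral-counting pipeline for case/control tissue
    proteomics. Converts search-engine PSM scores into posterior probabilities
    with a two-component Gaussian mixture, estimates decoy-based q-values and
    binned local FDR, resolves shared peptides into parsimony protein groups,
    quantifies proteins by normalized spectral counts with explicit
    infinite-fold-change semantics, partitions proteins into control-only /
    cancer-only / shared sets ("all or nothing" analysis), attributes
    cancer-only proteins to histological subtypes, screens them against
    knowledge lists to nominate novel candidates, and tests annotation-set
    over-representation. Ships a synthetic PSM generator with planted ground
    truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
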