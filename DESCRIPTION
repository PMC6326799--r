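Package: periFISH
Title: Nuclear-Border Coordinates, smFISH Molecule Classification and
    Nuclear-Proteome Enrichment for Co-Transcriptional mRNA Export
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit for studying mRNA export at the nuclear
    periphery of trypanosomes. Implements a DAPI-profile coordinate system
    (percent-of-peak normalization with pore-marker and cytoplasmic-marker
    border calibration), detection and grouping of multi-colour single
    molecule FISH spots into molecules with species and
    nucleus/periphery/cytoplasm classification, a 5'-first export
    orientation statistic, an S0-moderated Welch test with permutation
    false discovery rate for label-free nuclear proteome enrichment
    (including missing-not-at-random imputation), glutamine-rich 60-mer
    window scanning and reciprocal-best-hit homology classification. A
    synthetic-data module generates ground-truthed image stacks, LFQ
    matrices, protein sequences and homology tables so every stage can be
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
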