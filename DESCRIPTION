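Package: pgkevo
Title: Growth Kinetics, Fitness Landscapes and Codon Networks for
    Active-Site Divergence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying how essential, highly conserved
    active-site residues diverge, modeled on the lysine/serine exchange at
    position 219 of phosphoglycerate kinase (PGK). Implements a sliding-window
    plate-reader growth-rate and doubling-time estimator, catalytic-efficiency
    estimation from linear-regime initial rates, complete multi-locus
    genotype-fitness landscapes with mutational-trajectory enumeration,
    selection-threshold accessibility and pairwise epistasis classification
    (magnitude, sign, reciprocal sign), genetic-code mutational-network
    analytics (degenerate-codon expansion, minimum nucleotide distances,
    bridging amino acids), alignment-column composition and covariation by
    clade, variant-round fixation analysis, and seeded synthetic-data
    generators so that every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
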