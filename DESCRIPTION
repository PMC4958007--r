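Package: repadapt
Title: Parallelism, Epistasis and Clonal Dynamics in Replicate Experimental Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of replicate microbial adaptation experiments
    that sequence clonal isolates from many evolved populations. Provides a data
    model for mutation-by-isolate tables with genome annotation, pairwise
    parallelism between replicate populations at the nucleotide and
    regulatory/codon levels, randomization tests for genetic-background effects,
    three complementary epistasis analyses (within/between parallelism ratio, a
    mutation-by-background likelihood-ratio framework with stepwise removal of
    influential mutations, and pairwise co-occurrence randomization), reversion
    probability tests, within-population parsimony trees with clonal-dynamics
    classification, selection-coefficient estimation from competition
    trajectories, lysis-curve summarization, and a calibrated synthetic-data
    generator with a truth record so every analysis can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
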