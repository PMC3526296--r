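Package: cneloss
Title: Detection and Statistical Analysis of Conserved Non-Coding Element Losses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect complete losses of conserved non-coding elements
    (CNEs) from syntenic alignment evidence with strict artifact filters, to
    infer the phylogenetic branch of each loss by parsimony in the presence of
    missing data, and to test whether the number of independently lost elements
    exceeds the expectation under uniform per-branch loss frequencies, using
    both an exact combinatorial expectation and a constrained Monte-Carlo
    reassignment simulation. Includes catalog filtering of candidate elements,
    assembly validation by spanning sequencing reads, deletion-size analysis,
    genomic-context characterization of independently lost elements, and a
    coordinate-level synthetic data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
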