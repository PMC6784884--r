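Package: polysub
Title: Subgenome Analysis of Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the two subgenomes of allopolyploid plants
    such as interspecific banana hybrids. Identifies homoeologous gene pairs
    from pairwise alignment tables using cumulative identity percentage (CIP)
    and cumulative alignment length percentage (CALP) filters, calls
    homoeologous exchanges and whole-chromosome replacements from windowed
    unique-read coverage depth by maximum-likelihood copy-state
    classification, summarises genome constitution (e.g. "8A+25B"),
    classifies homoeologue expression dominance from replicated read counts
    with an exact conditional binomial test and Benjamini-Hochberg
    correction, quantifies dosage compensation against the genomic
    copy-number expectation, and computes Nei-Gojobori (1986) Ka/Ks and the
    transversion rate at fourfold-degenerate sites (4dTv) on codon
    alignments. A synthetic-data generator with full ground truth makes
    every stage testable without sequencing data.
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
    optparse
Config/testthat/edition: 3
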