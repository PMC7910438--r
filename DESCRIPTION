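Package: TailSeqR
Title: Calling, Profiling and Modelling of mRNA 3' Tails from Targeted
    3'-End Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying mRNA poly(A) tail metabolism and 3' terminal
    uridylation from targeted 3'-end sequencing libraries. Decomposes each
    read's 3' tail into its poly(A) stretch, terminal uridines and internal
    non-A content; aggregates calls into tail-length distributions, per-gene
    uridylation percentages and genotype comparisons; provides a
    quasi-likelihood negative-binomial pipeline for spectral-count and
    small-RNA enrichment analyses, quasi-Poisson half-life estimation for
    deadenylation time courses, and short-linear-motif scanning in protein
    sequences. A synthetic-data module generates every input with ground
    truth so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    limma,
    jsonlite,
    withr,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
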