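Package: taxq
Title: Penalty-Score Taxonomic Assignment of Ambiguous Sequencing Reads
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns ambiguous metagenomic sequencing reads to nodes of a
    rooted reference taxonomy by minimizing a penalty score parameterized by
    a single weight q in [0,1] that balances precision against recall.
    Setting q = 1 recovers the classical lowest-common-ancestor (LCA)
    assignment, q = 0 places every read at a leaf, and q = 0.5 is equivalent
    to maximizing the F-measure. The optimum is found in time linear in the
    number of matched reference sequences by restricting the search to the
    topological restriction of the taxonomy to the hit set, after a one-off
    linear-time preprocessing of the taxonomy (postorder numbering,
    constant-time LCA queries, subtree leaf counts). The package also
    provides ROC-space validation metrics against known true source leaves
    (signed distances to the diagonal, the per-q goodness statistic, an
    expected-distance statistic usable without ground truth, and a per-read
    best-q selection rule), readers for hit tables and BLAST tabular output
    with e-value tie grouping, a naive k-mismatch matcher, and a simulator
    of ranked taxonomies, reference sequences and error-bearing amplicon
    reads with known source leaves for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Metagenomics, Microbiome, Classification, Sequencing
RoxygenNote: 7.3.3
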