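Package: rwrboost
Title: Network Boosting of miRNA and mRNA Signatures by Random Walk with
    Restart
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated analysis of differentially expressed miRNAs and
    mRNAs over a protein-protein interaction network. Seed genes are formed
    from differentially expressed genes and the targets of differentially
    expressed miRNAs, propagated by Random Walk with Restart over a
    confidence-filtered STRING-style network, and extended into "boosted"
    gene sets at chosen boosting levels. Boosted sets are tested for
    pathway enrichment with an exact hypergeometric test, with a
    size-matched permutation null for the number of enriched pathways,
    hub-gene centrality reports, and miRNA-gene overlay network export.
    Includes a synthetic-fixture generator so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
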