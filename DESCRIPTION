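Package: glpapnet
Title: Pathway Activation, Crosstalk Networks and Network Propagation for
    Graft-Loss Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects candidate causes of late xenograft loss from
    peripheral-blood expression profiles. Scores per-pathway up-regulation
    with a competitive permutation test on gene-level log2 fold changes,
    intersects two comparisons (graft-losing vs. stable timepoint within the
    failing subject; failing vs. stable subject at the graft-losing
    timepoint) into a set of graft-loss-period activated pathways (GLPAPs),
    tests category enrichment with one-sided Fisher's exact tests, builds a
    pathway crosstalk network over a protein-protein interaction graph and
    selects central pathways by above-average closeness centrality and
    degree, and evaluates etiological hypotheses by random-walk-with-restart
    network propagation from seed genes, rank correlation against the
    differential-expression profile, and empirical p-values from random seed
    simulations. Includes a synthetic-data generator with a ground-truth
    manifest so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Matrix,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
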