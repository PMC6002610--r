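Package: enrichseq
Title: Transcriptomic Analysis of Environmental Enrichment Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for bulk RNA-seq studies of
    environmental enrichment in a litter-matched two-treatment,
    two-timepoint design. Provides transcript-to-gene aggregation, a
    group-wise TPM expression filter, trimmed-mean-of-M-values (TMM)
    normalisation, threshold-based differential expression calling,
    a gene-signature randomisation test on median fold changes, and
    Pearson correlation networks clustered with a Markov Clustering
    (MCL) implementation. Includes a negative-binomial synthetic-data
    generator with litter random effects and transient or persistent
    signature effects, used to validate every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    fgsea,
    rlang
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    mclust,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
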