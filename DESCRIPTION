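Package: coldregulon
Title: Cross-Species Cold-Stress Regulon Reconstruction from Expression
    Time Courses and Promoter Cis-Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative reconstruction of cold-stress transcriptional
    regulons across two related rice genotypes. Starting from replicated
    RNA-seq count time courses, promoter sequences and transcript
    alignment hit tables, the package establishes one-to-one ortholog
    pairs by longest-alignment and most-stable-mapping rules, tests
    per-timepoint differential expression with a negative-binomial
    likelihood-ratio test, classifies genes as cold-upregulated,
    downregulated or unchanged, quantifies cross-species concordance over
    ortholog pairs, clusters temporal profiles with negative-binomial
    model-based K-means, scans promoters for IUPAC cis-element motifs
    with positional enrichment scoring and motif-density classes, and
    assembles hub-centered co-expression networks whose fragmentation is
    compared between genotypes. A synthetic-data generator with planted
    ground truth (differential expression, co-expression modules, motif
    placements) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
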