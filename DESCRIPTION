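Package: gwaspan
Title: Post-GWAS Candidate Gene Prioritization with Pangenome Lift-Over
    and Coexpression Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-references GWAS/QTL genomic intervals with gene
    annotations, pairwise whole-genome alignments, ortholog groups,
    weighted coexpression networks, ontology and pathway gene sets,
    transcription-factor binding sites and literature-mined entity
    annotations to produce ranked candidate-gene reports. Implements
    overlapping community detection (cohesiveness-based greedy growth and
    a triangle-approximation weighted community clustering variant),
    one-tailed Fisher module enrichment and overrepresentation analysis
    with Benjamini-Hochberg control, interval lift-over through one-to-one
    ungapped alignment segments with ortholog-partition reporting, and a
    Monte-Carlo shuffle test for binding-site overlap enrichment. A
    synthetic-fixture generator emulates every consumed file format so the
    whole pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
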