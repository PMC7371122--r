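Package: fesmgc
Title: Phylogenomic Profiling of Fe-S Flavoenzyme Metabolic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects dual-domain Fe-S flavoenzyme anchor genes in annotated
    bacterial genomes from hmmsearch-style domain hit tables, profiles their
    copy numbers and prevalence across taxa, extracts same-strand metabolic
    gene clusters around each anchor under a bounded intergenic-gap rule,
    groups clusters into families through a Jaccard/adjacency domain-content
    similarity network, and predicts substrate-category functions from Pfam
    domain content. A synthetic-genome generator plants anchors, clusters,
    families and copy-number laws with known truth so that every stage of the
    pipeline can be validated end to end without external downloads. Includes
    a small phylogenetics toolkit (greedy identity clustering, alignment
    trimming and concatenation, neighbor joining, midpoint and outgroup
    rooting, N50 filtering) mirroring the enzyme-family workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    Biostrings,
    rtracklayer,
    phangorn,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
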