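Package: ecrscan
Title: Discovery and Quantification of Edited Double-Stranded RNA Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-caller analysis pipeline for endogenous double-stranded RNA
    surveillance studies. Discovers A-to-I editing clusters from strand-resolved
    pileup base counts through a staged filter cascade, builds padded and merged
    editing-cluster-rich regions (ECRs) for expression quantification, derives
    intron regions from principal-isoform annotation, quantifies relative splice
    site usage and repeat-class stratification of splicing clusters, performs
    feature-level differential expression with gene-normalized library sizes and
    a 2x2 factorial interaction test for interferon-stimulated genes, scores
    dsRNA secondary structures as candidate MDA5 ligands, and ranks repeat
    families by eCLIP enrichment. Includes a seedable synthetic-data generator
    that plants ground truth for every analysis stage so the full pipeline is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    edgeR,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
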