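Package: asRNAclass
Title: Classification of Genes by the Behaviour of Rrp6-Sensitive Antisense RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide classification of budding-yeast genes by the behaviour of
    their exosome (Rrp6)-sensitive antisense RNAs across histone-modifier mutants.
    Builds strand-specific binned differential-expression features from tiling
    log2-intensity tracks, clusters genes with a deterministic partitioning-around-
    medoids implementation, assesses cluster robustness by subsampled consensus
    clustering, and groups clusters into silencing classes. Includes downstream
    characterisation: antisense metagene profiles, Nrd1/Nab3 termination-motif and
    PAR-CLiP binding scoring, promoter-structure and H3K4me3 enrichment analyses,
    ncRNA segmentation with CUT/SUT annotation, RNA half-life estimation, and a
    fully synthetic study generator with planted class structure for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    withr,
    data.table,
    yaml,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
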