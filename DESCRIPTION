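Package: rareCNV
Title: Rare Germline Copy-Number Variant Calling and Gene-Centric Association Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of rare germline copy-number variants (CNVs)
    from SNP-array intensity data. Implements derivative log ratio spread (DLRS)
    sample quality control, principal-component adjustment of Log R Ratio (LRR)
    intensities to remove genomic waves and batch effects, penalised mean-shift
    segmentation of per-probe z-scores for rare CNV calling, gene and exon
    annotation, case-control global CNV burden analysis, three gene-centric
    CNV association models (deletion-only, duplication-only and loss-of-function)
    with Bonferroni thresholds and Wakefield Bayesian false discovery
    probabilities, and downstream risk-SNP colocalisation, over-representation
    and dosage-sensitivity analyses. A synthetic cohort generator with known
    embedded CNV truth makes every stage testable without accession data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    data.table,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CopyNumberVariation, GenomeWideAssociationStudy, QualityControl,
    StatisticalMethod, SNP
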