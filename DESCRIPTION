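Package: gwastargets
Title: Integrative Identification of GWAS-Locus Target Genes in a Cell Type
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for nominating target genes of GWAS risk
    loci in a cell type of interest. Combines eQTL-based SNP-gene association
    filtering, rank-product meta-analysis of case/control expression studies
    with permutation-estimated proportion of false positives (PFP),
    SNP-to-gene integration with histone-mark interval overlap and
    covariate-adjusted methylation-QTL regression, and first-order
    protein-protein interaction subnetwork construction with hypergeometric
    pathway enrichment and permutation-derived empirical pathway P-values.
    Ships a seeded synthetic-data generator emulating the statistical
    structure of each input so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
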