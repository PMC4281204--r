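Package: focalCNA
Title: Candidate Driver Gene Nomination from Focal Somatic Copy-Number
    Aberrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nominates candidate cancer driver genes by integrating focal
    (<= 3 Mb) somatic copy-number aberrations with expression data, as used in
    SNP-array studies of osteosarcoma. Provides median and mode normalization
    and circular binary segmentation of probe-level log2ratio profiles,
    threshold-based gain/loss calling, two-rule germline copy-number-variant
    filtering (catalog overlap and recurrent bidirectionality),
    smallest-overlap high-frequency-region (HFR) computation with focal and
    total sample counts, gene-to-HFR mapping, fold-change concordance scoring
    against a reference expression profile with a frequency-of-involvement
    rule, confirmation in an independent expression set, hypergeometric
    census-gene enrichment and rank-sum cohort-frequency comparison, plus a
    synthetic cohort generator with planted ground truth so the whole pipeline
    is testable without external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    limma,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
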