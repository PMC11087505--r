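Package: demuxbulk
Title: Donor Deconvolution of Multiplexed Bulk RNA-Seq from Expressed Allelic Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the proportion of each genotyped donor in a pooled
    (multiplexed) bulk RNA-seq sample from ALT/REF read counts at biallelic
    SNPs, using a binomial mixture over donor genotypes fitted by
    expectation-maximization, and detects genes differentially expressed
    between donors with a chi-square likelihood-ratio test on gene-level
    donor abundance. Includes readers for multi-sample genotype VCFs and
    cellSNP-lite-style allelic count outputs (VCF with AD/DP tags, or sparse
    MatrixMarket trios), a synthetic-data generator covering pseudo-bulk
    aggregation, read down-sampling, doublet injection and donor-specific
    expression effects, and an evaluation harness reporting Jensen-Shannon
    divergence and Pearson correlation of recovered compositions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
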