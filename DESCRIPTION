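Package: comparascan
Title: Comparative Genomic Scans for Multi-Species Diploid Panels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sliding-window and per-site heterozygosity, PLINK-style
    detection of runs of homozygosity with length-class summaries,
    lineage-private allele enrichment scans over regulatory flanking
    windows of transcripts, unique high-impact variant filtering, and
    homozygous-derived damaging-genotype load, for multi-sample diploid
    VCF panels spanning several species. Includes a multi-species
    genotype simulator with implanted autozygous tracts and
    enrichment-aware private-allele injection that emits truth files,
    so every stage of the pipeline can be verified by parameter
    recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    vcfR,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
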