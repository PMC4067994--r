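Package: PanelCNV
Title: Read-Depth Copy Number Variant Detection for Targeted Deafness Gene Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exon-level copy number variant (CNV) detection from targeted
    genomic enrichment sequencing depth, built for clinical deafness gene
    panels. Implements batch-normalized median read-depth ratios with
    sliding-window smoothing, copy-state segmentation into deletion and
    duplication calls, pseudogene-aware gene-conversion calling for
    segmental-duplication loci such as STRC, STRC/CATSPER2 locus diagnosis
    including deafness-infertility syndrome, per-patient causative-category
    assignment and cohort summarization with carrier-frequency estimation,
    and repetitive-element (Alu/L1/segmental duplication) burden comparison
    between genes. Includes a seeded negative-binomial simulator of targeted
    capture cohorts with spiked CNVs and gene conversions so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CopyNumberVariation, CNV, Sequencing, Coverage, GeneticVariability
RoxygenNote: 7.3.3
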