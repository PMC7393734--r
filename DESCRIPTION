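Package: somaticburden
Title: Somatic Mutation Burden and Hotspot Enrichment Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-level somatic mutation enrichment analysis for tumor
    cohorts from whole-genome or exome variant calls. Provides a coding
    pipeline (non-silent mutation burden in genes from GTF models) and a
    noncoding pipeline (mutation burden in user-defined BED regions, e.g.
    promoters or enhancers), both with configurable background mutation-rate
    estimation (global, local windowed, covariate-clustered via affinity
    propagation, and a local-clustered hybrid), binomial and negative-binomial
    burden tests, gap-based hotspot detection with direct sub-region testing,
    a permutation-based weighted average proximity (WAP) clustering test,
    Fisher combination of component p-values, and Benjamini-Hochberg FDR
    control. Includes a synthetic-cohort generator (toy genome FASTA, GTF,
    BED, bgzip+tabix VCFs) with planted enrichments and hotspots for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    VariantAnnotation,
    rtracklayer,
    Biostrings,
    data.table,
    parallel,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
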