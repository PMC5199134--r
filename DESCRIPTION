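Package: sliderSelect
Title: Slider-Style Selection of Genomic Features by Expression Contribution
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects genes, promoters, enhancers and other genomic features
    that are preferentially active in chosen cells or tissues. Expression
    values are normalized per feature to percentage contributions across the
    facets (cell/tissue groups) of a panel, and features are selected by
    closed interval ("slider") constraints on those percentages, combined
    across panels with AND/OR logic. Includes ordinal immunohistochemistry
    constraints for dual RNA/protein selection, genomic filters (region and
    gene-TSS-window selection, enhancer-SNP midpoint overlap, enhancer to
    promoter association lookup), readers and writers for the standard
    formats involved (TSV/GCT expression tables, BED with UCSC track lines,
    FASTA with flanks, VCF positions), and deterministic synthetic-data
    generators for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
biocViews: GeneExpression, Transcription, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'conditions.R'
    'constructors.R'
    'core-model.R'
    'fixtures.R'
    'genomic-filters.R'
    'io-formats.R'
    'selection.R'
    'sliderSelect-package.R'
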