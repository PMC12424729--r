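Package: nucleatR
Title: Classification of PRC2 De Novo Nucleation Sites from Degron ChIP-seq Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies and characterises Polycomb Repressive Complex 2 (PRC2)
    de novo nucleation sites from a three-condition auxin-degron ChIP-seq
    design (steady state, auxin depletion, reintroduction). Provides a
    negative-binomial Wald test over union peak counts with median-of-ratios
    normalisation, a dual-contrast peak classifier (nucleation,
    control-exclusive, persistent, newly acquired), background-matched
    resampling enrichment with empirical p-values and Fisher exact tests,
    CpG-island methylation-status calling, chromatin-loop anchor analysis
    with Aggregate Peak Analysis and virtual 4C, and a fully seeded
    synthetic-data generator that plants ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    data.table
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ChIPSeq, Epigenetics, DifferentialPeakCalling, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classify.R'
    'diffbind.R'
    'enrichment.R'
    'io.R'
    'loops.R'
    'methods.R'
    'methylation.R'
    'nucleatR-package.R'
    'simulate.R'
    'pipeline.R'
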