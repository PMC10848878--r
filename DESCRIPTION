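Package: svload
Title: Structural-Variant Filtering, Polarization and Genetic Load Analysis
    for Pedigree-Structured Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genetic analysis of structural variants
    (deletions, duplications, inversions) genotyped from short-read data in
    small, pedigree-structured populations. Implements the quality and
    genotype-frequency filter cascade used with smoove/duphold-style calls
    (depth fold-change and heterozygosity-score thresholds, curation-decision
    files), trio-based Mendelian validation and PCA batch diagnostics,
    gene-overlap classification, repeat composition and length spectra,
    two-outgroup allele polarization with mutation-type reclassification,
    unfolded site frequency spectra with goodness-of-fit comparison, masked
    and realized genetic load per individual and generation class, and
    fixation/genetic-rescue accounting after immigration. A pedigree-aware
    synthetic cohort generator with known ground truth (gene dropping from a
    three-founder bottleneck, immigrant matings, injected low-quality
    artifacts) makes every stage testable without access to sequencing data.
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
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: StructuralVariation, VariantAnnotation, PopulationGenetics,
    Genetics, QualityControl
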