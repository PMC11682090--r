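Package: moiscan
Title: Mode-of-Inheritance Stratified Private Variant Filtering and
    Homozygosity Mapping for Rare-Disorder Candidate Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens multi-sample whole-genome variant calls for candidate
    causal variants of rare Mendelian disorders in livestock cohorts.
    Implements mode-of-inheritance stratified private-variant filtering of
    case genomes against tiered control cohorts (recessive shared across
    cases, recessive per case, dominant per case) with a configurable
    protein-changing annotation filter and per-case filtering funnels;
    consecutive-runs detection of runs of homozygosity, cross-case shared
    homozygous regions and the genomic inbreeding coefficient F_ROH;
    per-population genotype counts and allele frequencies for target
    variants; and an evidence-based candidate classification cascade
    (likely pathogenic / uncertain significance). A seeded cohort simulator
    with planted causal variants and homozygosity blocks provides a
    machine-readable truth table so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
biocViews: VariantDetection, GenomicVariation, SNP, Sequencing, Genetics
RoxygenNote: 7.3.3
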