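Package: snpXval
Title: Cross-Platform SNP Discovery and In Silico Validation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for bioinformatic validation of single-nucleotide
    polymorphisms discovered from low-coverage, multi-chemistry resequencing
    data. Implements low-stringency pileup heterozygote calling, exact-match
    31bp allele-specific probe genotyping ("e-genotyping") in base space and
    SOLiD di-base colour space, pairwise cross-chemistry and cross-animal
    positional-allele validation with deduplicated merging, collapsed-duplication
    artifact screens (coverage-distribution comparison and probe scanning of
    unplaced assembly sequence), genomic-context annotation against gene models,
    and evaluation statistics (genotype concordance, validation efficiency,
    per-chromosome SNP density, cross-species positional overlap). Ships a
    multi-chemistry diploid read simulator with known truth for end-to-end
    exercise of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'annotate.R'
    'colorspace.R'
    'core-io.R'
    'crossval.R'
    'dupscreen.R'
    'egenotype.R'
    'evalstats.R'
    'hetcaller.R'
    'pipeline.R'
    'published.R'
    'simdata.R'
    'snpXval-package.R'
    'utils.R'
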