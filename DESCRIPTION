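Package: snpgem
Title: RNA-Seq Genotyping and Genomic Characterization of Breeding Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize small, highly heterozygous plant breeding
    collections from RNA-seq derived data: per-sample genotype calling from
    allele read depths with a depth/frequency/quality filter cascade,
    nucleotide diversity and Tajima's D, method-of-moments inbreeding and
    identity-by-descent relatedness, population structure from SNPs and from
    gene expression markers (GEMs), synteny-projected linkage disequilibrium
    and Gabriel-style haplotype blocks, kinship-corrected mixed-model SNP
    association, and expression-marker trait association. Includes a
    synthetic open-pollinated breeding-collection simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
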