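Package: poolrens
Title: Population Genetics of Pooled R-Gene Enrichment Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled target-enrichment resequencing of plant
    resistance (NLR) genes within a single population. Detects SNPs from pooled
    per-site allele counts with explicit depth and minor-allele-count thresholds,
    masks indel-proximal and excess-coverage regions, intersects and validates
    independent call sets, computes pooled nucleotide diversity and Nei-Gojobori
    piN/piS per gene, builds folded site-frequency spectra from pooled minor-allele
    frequencies, and models heterozygosity decay in a partially selfing, serially
    bottlenecked germplasm population (with inversion to initial heterozygosity and
    a Wright-Fisher forward simulator). Includes a synthetic-data generator that
    emulates the pooled enrichment design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
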