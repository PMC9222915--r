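Package: csdTyper
Title: Diploid csd Hypervariable-Region Allele Typing from Short Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reconstructs the two alleles of the honeybee complementary
    sex-determiner (csd) hypervariable region (HVR) carried by a diploid
    worker bee from whole-genome short reads. Reads overlapping the HVR
    interval of csd exon 7 are extracted from alignments, clustered by a
    greedy overlap-layout-consensus assembler (minimum overlap 40 bp,
    minimum identity 90 percent), translated in all six frames, and
    validated against the SSLS...IEQI peptide motif that delimits the HVR.
    Per-sample genotypes feed an allele catalogue with population and
    per-subspecies frequencies, private/shared-allele classes, a
    neighbor-joining peptide tree, and a packaged reference catalogue of
    88 published HVR alleles. A fully seeded read simulator generates
    diploid cohorts with truth tables so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    ape,
    phytools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
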