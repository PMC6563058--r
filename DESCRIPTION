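Package: wgha
Title: Whole-Genome Homozygosity Analysis for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and case-control association analysis of runs of
    homozygosity (ROH) in SNP genotype panels. Reads and writes PLINK-style
    .bed/.bim/.fam triplets, applies marker and sample quality control
    (call rate, minor allele frequency, exact Hardy-Weinberg test),
    calibrates a cohort-specific minimum ROH length from mean
    heterozygosity with a linkage-disequilibrium tag-group correction,
    calls broad-sense ROH with a heterozygote-tolerant sliding window,
    builds consensus ("common") ROH regions, tests regions and global ROH
    burden for case-control association, and pools two cohorts by
    fixed-effects inverse-variance meta-analysis. A synthetic cohort
    generator with block linkage disequilibrium and planted autozygous
    tracts supports calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
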