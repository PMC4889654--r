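Package: ldscreen
Title: SNP Filtering, Linkage-Disequilibrium Decay and Beta-Outlier
    Selection Screens for Reduced-Representation Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide SNP panels from reduced-representation
    (ddRAD-style) sequencing of structured insect populations. Implements a
    depth/missingness/allele-frequency filtering cascade for biallelic SNP
    genotypes, diversity and differentiation summaries (observed
    heterozygosity, windowed nucleotide diversity and Tajima's D, exact
    Hardy-Weinberg tests with Bonferroni and Benjamini-Hochberg correction,
    Weir-Cockerham Fst), distance-binned linkage-disequilibrium (LD) decay
    estimation with loess smoothing and half-decay distances, a per-bin
    Beta-distribution outlier test that assigns tail probabilities to
    SNP pairs with unusually high LD, and a selection screen intersecting
    top-ranked loci from an external Fst outlier scan with LD-flagged pairs
    and nearby gene annotations. A haplotype-copying simulator with
    analytically known LD decay and Balding-Nichols population structure
    provides fixtures with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    fitdistrplus
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
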