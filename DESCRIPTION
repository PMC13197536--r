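Package: apricotMAS
Title: Marker-Assisted Selection for Apricot Fruit Skin Color
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genotype-phenotype analysis of apricot (Prunus
    armeniaca) fruit skin color. Converts CIELAB colorimeter readings into
    hue-angle phenotype classes (orange, light orange, yellow), scores
    concordance between SNP or SSR marker genotypes and observed skin color
    with unweighted and class-weighted efficiency statistics, reconstructs
    candidate-gene alleles from sequence (in-silico PCR, AGC tandem-repeat
    sizing, SNP-state extraction, haplotype assembly against a four-allele
    table), and translates alleles into protein variants carrying a
    variable-length polyalanine tract and His/Tyr substitutions. Includes a
    synthetic cohort and allele-sequence simulator so every pipeline stage is
    testable without external data, plus genotype and hue tables for a
    40-seedling breeding population and a 57-cultivar panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, SNP, Microsatellite, SequenceMatching, Classification
RoxygenNote: 7.3.3
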