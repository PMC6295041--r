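Package: StepBLUP
Title: Single-Step Genomic BLUP Evaluation for Family-Structured Breeding
    Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Pedigree and single-step genomic BLUP (ssGBLUP) evaluation for
    family-structured aquaculture breeding programs. Provides numerator
    relationship matrices and their sparse inverses (Henderson's rules with
    Meuwissen-Luo inbreeding), VanRaden genomic relationship matrices with
    A22 blending and H-inverse assembly, Henderson's mixed-model equations
    with a full-sib common-environment effect, EM-REML variance components,
    four training/validation designs with predictive-ability and inflation
    metrics, weighted ssGBLUP association scans with 20-SNP window variances,
    linkage-disequilibrium decay and effective-population-size estimation
    (Sved curve and rate of inbreeding), and a gene-drop simulator producing
    genotypes and phenotypes with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
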