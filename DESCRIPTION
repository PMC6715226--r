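Package: ssgblup
Title: Single-Step Genomic BLUP for Partially Genotyped Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree, genomic, and combined (single-step) relationship
    matrices and REML/BLUP genetic evaluation for breeding populations in
    which only a subset of individuals is genotyped. Builds the numerator
    relationship matrix A (with inbreeding) and its inverse, the VanRaden
    method-1 genomic relationship matrix G with SNP quality control, and
    the combined H matrix with tunable blending (alpha, beta) and scaling
    (tau, omega) parameters. Fits the linear mixed model y = Xb + Zu + e
    by exact restricted maximum likelihood for any relationship kernel,
    predicts breeding and genotypic values, and evaluates prediction
    accuracy by leave-one-family-out cross-validation for genotyped and
    non-genotyped individuals. Includes a gene-dropping simulator that
    emulates a fruit-tree breeding population of pair-cross families for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
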