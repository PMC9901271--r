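Package: ssram
Title: Single-Step Genomic Evaluation with Reduced Animal Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-step genomic evaluation of pedigreed populations by
    ssGBLUP and the single-step marker model, together with three reduced
    animal model (RAM) formulations that shrink Henderson's mixed-model
    equations to subsets of animals (genotyped animals plus nongenotyped
    parents, nongenotyped phenotyped animals, or nongenotyped parents of
    phenotyped nongenotyped nonparents) and recover the remaining breeding
    values exactly by back-solving on Mendelian-sampling regressions or
    sparse pedigree-inverse blocks. Includes pedigree validation and
    classification, numerator relationship machinery (tabular A,
    Meuwissen-Luo inbreeding, Henderson's sparse A-inverse, Schur-complement
    subset inverses), VanRaden genomic relationship matrices, genotype
    imputation for nongenotyped animals, a gene-dropping simulator, and
    plain-text interchange formats with a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'ssram-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'pedigree.R'
    'relationship.R'
    'genomic.R'
    'evaluation.R'
    'ram.R'
    'markermodel.R'
    'io.R'
    'example.R'
    'simulate.R'
    'cli.R'
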