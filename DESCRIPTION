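Package: biofortqg
Title: Quantitative Genetics of Biofortified Cassava Germplasm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multi-environment augmented-block-design
    evaluations of cassava germplasm. Derives root-quality and yield traits
    from raw field and laboratory measurements (gravimetric and oven-dry dry
    matter content, spectrophotometric total carotenoid content, per-hectare
    yields, harvest index), fits the per-trait mixed model by REML with fixed
    check effects and random genotype, trial, block and genotype-by-trial
    terms, extracts BLUPs, estimates broad-sense and clonal-mean
    heritabilities, tests model terms by likelihood-ratio deviance, builds
    Pearson and regularized partial-correlation trait networks, clusters
    genotypes by PCA/K-means with BIC model selection, and computes
    weighted-BLUP selection indices with predicted genetic gains. Includes a
    synthetic multi-environment trial generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
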