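Package: phenodiv
Title: Phenotypic Diversity Evaluation of Crop Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating phenotypic diversity in crop germplasm
    collections, built around the workflow used for large foxtail millet
    (Setaria italica) accession panels. Provides a trait registry for
    quantitative and coded qualitative descriptors, descriptive
    variability statistics (coefficient of variation), Shannon-Wiener
    diversity indices with mean/standard-deviation 10-class
    stratification of continuous traits, Pearson correlation analysis,
    principal component analysis on the trait correlation matrix with
    contribution rates and score coefficients, a contribution-rate
    weighted composite F-score for accession ranking, Ward hierarchical
    clustering into phenotype groups, and a seedable synthetic-cohort
    generator that emulates published marginal trait distributions for
    testing the full pipeline without access to raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, mclust, ape, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
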