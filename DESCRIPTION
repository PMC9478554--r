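Package: AngoraGS
Title: Genomic Prediction for Repeatedly Measured Wool Traits by GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic selection in small livestock populations with
    traits recorded at several ages, modelled on Angora rabbit wool and body
    weight records taken at 70, 140 and 210 days. Provides genotype input
    (PLINK bed/bim/fam, VCF, dosage CSV) with marker quality control (MAF,
    missing rate, Hardy-Weinberg exact test), VanRaden genomic relationship
    matrices, exact eigendecomposition REML for the univariate genomic animal
    model and EM/AI-REML for the three-age multivariate model with arbitrary
    missing-record patterns, GEBV prediction for unphenotyped animals,
    10-fold cross-validation with partial-record leave-out strategies,
    marker-density subsampling experiments, and a synthetic population
    generator with known breeding values for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'AngoraGS-package.R'
    'genio.R'
    'simulate.R'
    'grm.R'
    'reml-uv.R'
    'reml-mv.R'
    'evaluate.R'
    'config.R'
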